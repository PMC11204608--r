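# Population summary statistics (mean, population STD, CV) and cohort
# report tables.

#' Population summary statistics
#'
#' Mean, population standard deviation (divisor n, not n - 1) and the
#' coefficient of variation in percent, `100 * std / mean`.
#'
#' @param values numeric vector (n >= 1).
#' @param cv compute the CV (requires a non-zero mean).
#' @return an object of class `SummaryStats`: `n`, `mean`, `std`, `cv`.
#' @export
population_stats <- function(values, cv = TRUE) {
  x <- as.numeric(values)
  if (!length(x)) stop("cannot summarize an empty value list")
  if (any(!is.finite(x))) stop("values must be finite")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  cvv <- NA_real_
  if (cv) {
    if (m == 0) stop("CV is undefined for a zero mean")
    cvv <- 100 * s / m
  }
  structure(list(n = length(x), mean = m, std = s, cv = cvv),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("SummaryStats: n = %d, mean %.4f, STD %.4f, CV %.2f%%\n",
              x$n, x$mean, x$std, x$cv))
  invisible(x)
}

#' Mean of per-entity coefficients of variation
#'
#' Applies [population_stats()] to a column of CV values, as used for the
#' cohort-level "mean CV" summaries of bone volumes, surface areas, femoral
#' parameters and attachment areas.
#'
#' @param table data frame with a CV column, or a bare numeric vector.
#' @param metric name of the CV column (default `"cv"`).
#' @return a `SummaryStats`.
#' @export
mean_of_cvs <- function(table, metric = "cv") {
  x <- if (is.numeric(table)) table else {
    if (!metric %in% names(table))
      stop("no column '", metric, "' in the table")
    table[[metric]]
  }
  population_stats(x)
}

#' Aggregate a muscle complex from component mean areas
#'
#' Sums component mean footprint areas (e.g. the conjoined hamstring
#' tendon from the long biceps head and semitendinosus origins), recording
#' component provenance.
#'
#' @param component_means named numeric vector or list (mm^2).
#' @return total area (mm^2) with attribute `components`.
#' @export
aggregate_complex <- function(component_means) {
  x <- unlist(component_means)
  if (!length(x)) stop("no components to aggregate")
  out <- sum(x)
  attr(out, "components") <- x
  out
}

.summary_row <- function(entity, metric, values) {
  st <- population_stats(values, cv = mean(values) != 0)
  data.frame(entity = entity, metric = metric, n = st$n,
             mean = round_half_away(st$mean, 2),
             std = round_half_away(st$std, 2),
             cv = if (is.na(st$cv)) NA_real_ else round_half_away(st$cv, 2))
}

#' Render cohort report tables
#'
#' Builds the four report tables from per-specimen metric data frames:
#' deviations (specimen, bone, scan, mean_mm), bone morphology (specimen,
#' bone, volume_mm3, sa_mm2, cogx, cogy, cogz), femoral parameters
#' (specimen, ma, tea, fhd, sd) and attachments (specimen, attachment,
#' area_mm2, cx, cy, cz).  Values are rendered with 2-decimal
#' round-half-away-from-zero; summaries are computed from the unrounded
#' inputs.
#'
#' @param deviations,bones,femoral,attachments data frames (any may be
#'   `NULL` or empty and is then skipped).
#' @return named list of summary data frames (class `CohortTable`).
#' @export
render_tables <- function(deviations = NULL, bones = NULL, femoral = NULL,
                          attachments = NULL) {
  out <- list()
  chk <- function(df, need, what) {
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(what, " table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (!is.null(deviations) && nrow(deviations)) {
    chk(deviations, c("specimen", "bone", "mean_mm"), "deviation")
    rows <- lapply(split(deviations, deviations$bone), function(d)
      .summary_row(d$bone[1], "deviation_mm", d$mean_mm))
    rows$overall <- .summary_row("all", "deviation_mm", deviations$mean_mm)
    out$deviations <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  if (!is.null(bones) && nrow(bones)) {
    chk(bones, c("specimen", "bone", "volume_mm3", "sa_mm2"), "bone")
    rows <- list()
    for (b in unique(bones$bone)) {
      d <- bones[bones$bone == b, ]
      rows[[paste0(b, "_vol")]] <- .summary_row(b, "volume_mm3", d$volume_mm3)
      rows[[paste0(b, "_sa")]] <- .summary_row(b, "sa_mm2", d$sa_mm2)
    }
    out$bones <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  if (!is.null(femoral) && nrow(femoral)) {
    chk(femoral, c("specimen", "ma", "tea", "fhd", "sd"), "femoral")
    out$femoral <- do.call(rbind, c(lapply(c("ma", "tea", "fhd", "sd"),
      function(m) .summary_row("femur", m, femoral[[m]])),
      make.row.names = FALSE))
  }
  if (!is.null(attachments) && nrow(attachments)) {
    chk(attachments, c("specimen", "attachment", "area_mm2"), "attachment")
    rows <- lapply(split(attachments, attachments$attachment), function(d)
      .summary_row(d$attachment[1], "area_mm2", d$area_mm2))
    out$attachments <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  structure(out, class = "CohortTable")
}

#' @export
print.CohortTable <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print.data.frame(x[[nm]])
  }
  invisible(x)
}

#' Printed report tables bundled as fixtures
#'
#' Returns the per-specimen report tables shipped with the package under
#' `extdata/` (deviations, femoral parameters, per-entity CVs and mean
#' attachment areas of the reference cohort), used for statistics-layer
#' regression tests.
#'
#' @param name one of `"deviations"`, `"femoral"`, `"bone_cv"`,
#'   `"attachment"`.
#' @return a data frame.
#' @export
reference_table <- function(name = c("deviations", "femoral", "bone_cv",
                                     "attachment")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "ctfootprint", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
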
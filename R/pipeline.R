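# Pipeline driver: synthetic cohort -> repeat "scans" -> segmentation ->
# alignment and deviation -> coherent model -> ISB frame -> footprints ->
# cohort statistics, with per-specimen error isolation and a run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the reconstruction pipeline with its
#' conventional default: the primary bone HU window (250-3000), the
#' secondary paint threshold (2000 HU), the tracing distance (0.5 mm),
#' smoothing, deviation sampling, scan emulation and seeding.
#'
#' @param hu_min,hu_max primary bone window (HU).
#' @param paint_hu_min secondary paint threshold (HU).
#' @param trace_epsilon footprint tracing distance (mm).
#' @param smoothing_iters,smoothing_lambda Taubin smoothing of the coherent
#'   model.
#' @param deviation_samples surface samples per deviation analysis.
#' @param n_scans scans emulated per specimen (scan 1 is the reference).
#' @param spacing CT voxel spacing (mm).
#' @param noise_sd additive HU noise SD.
#' @param scan_angle_sd,scan_trans_sd inter-scan repositioning (degrees /
#'   mm).
#' @param seed master RNG seed.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(hu_min = 250, hu_max = 3000, paint_hu_min = 2000,
                            trace_epsilon = 0.5, smoothing_iters = 10L,
                            smoothing_lambda = 0.5,
                            deviation_samples = 10000L, n_scans = 3L,
                            spacing = 1.5, noise_sd = 15,
                            scan_angle_sd = 1, scan_trans_sd = 2,
                            seed = 1L) {
  for (v in c(hu_min, hu_max, paint_hu_min))
    if (v < -1024 || v > 4000) stop("HU thresholds must lie in [-1024, 4000]")
  if (hu_min >= hu_max) stop("hu_min must be below hu_max")
  if (trace_epsilon <= 0) stop("trace_epsilon must be positive")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(hu_min = hu_min, hu_max = hu_max,
                 paint_hu_min = paint_hu_min, trace_epsilon = trace_epsilon,
                 smoothing_iters = as.integer(smoothing_iters),
                 smoothing_lambda = smoothing_lambda,
                 deviation_samples = as.integer(deviation_samples),
                 n_scans = as.integer(n_scans), spacing = spacing,
                 noise_sd = noise_sd, scan_angle_sd = scan_angle_sd,
                 scan_trans_sd = scan_trans_sd, seed = as.integer(seed)),
            class = "PipelineConfig")
}

# reconstruct the bone and per-patch paint surfaces of one scan
.reconstruct_scan <- function(scene, config, seed) {
  vol <- voxelize_scene(scene, spacing = config$spacing,
                        noise_sd = config$noise_sd, seed = seed)
  primary <- threshold_segment(vol, config$hu_min, config$hu_max)
  lab <- split_paint(vol, primary, config$paint_hu_min)
  bone <- extract_surface(lab$bone, keep = "largest_component",
                          field_smoothing = 1L)
  paints <- NULL
  if (any(lab$paint$values)) {
    pm <- extract_surface(lab$paint, keep = "all", field_smoothing = 0L)
    comp <- mesh_components(pm)
    fc <- face_centroids(pm)
    ar <- face_areas(pm)
    truth_ctr <- t(vapply(scene$patches, `[[`, numeric(3), "truth_centroid"))
    lab_of <- integer(max(comp))
    for (ci in seq_len(max(comp))) {
      idx <- comp == ci
      ctr <- colSums(fc[idx, , drop = FALSE] * ar[idx]) / sum(ar[idx])
      dd <- rowSums(sweep(truth_ctr, 2, ctr)^2)
      lab_of[ci] <- which.min(dd)
    }
    paints <- list()
    for (j in seq_along(scene$patches)) {
      keep <- which(comp %in% which(lab_of == j))
      if (length(keep))
        paints[[names(scene$patches)[j]]] <- submesh(pm, keep)
    }
  }
  list(volume_warnings = attr(vol, "warnings"), bone = bone, paints = paints,
       landmarks = scene$landmarks)
}

.analyze_specimen <- function(scene0, config, specimen_id) {
  warnings <- character(0)
  # left-sided specimens are mirrored into the common right-side convention
  scene <- if (identical(scene0$side, "left")) mirror_scene(scene0) else scene0
  base_seed <- config$seed * 10000L + specimen_id * 100L
  scans <- list()
  dev_rows <- list()
  aligned <- list()
  for (s in seq_len(config$n_scans)) {
    sc_scene <- if (s == 1L) scene else
      perturb_scene(scene, angle_sd = config$scan_angle_sd,
                    trans_sd = config$scan_trans_sd, seed = base_seed + s)
    scans[[s]] <- .reconstruct_scan(sc_scene, config, seed = base_seed + s)
    warnings <- c(warnings, scans[[s]]$volume_warnings)
  }
  ref <- scans[[1]]
  for (s in seq.int(2L, length.out = config$n_scans - 1L)) {
    lm_mov <- do.call(rbind, scans[[s]]$landmarks)
    lm_fix <- do.call(rbind, ref$landmarks[names(scans[[s]]$landmarks)])
    tf <- rigid_align(scans[[s]]$bone, ref$bone,
                      init_landmarks = list(moving = lm_mov, fixed = lm_fix))
    mov <- transform_mesh(scans[[s]]$bone, tf$rotation, tf$translation)
    aligned[[length(aligned) + 1L]] <- mov
    dev <- with_seed(base_seed + 50L + s,
                     deviation_analysis(mov, ref$bone,
                                        n_samples = config$deviation_samples))
    dev_rows[[length(dev_rows) + 1L]] <- data.frame(
      specimen = specimen_id, bone = "femur", scan = paste0("CT", s),
      mean_mm = dev$mean, std_mm = dev$std)
  }
  # coherent model: the cleaned, smoothed reference reconstruction (repeat
  # scans contribute through the deviation analysis)
  coherent <- merge_and_clean(list(ref$bone),
                              smoothing_iters = config$smoothing_iters,
                              smoothing_lambda = config$smoothing_lambda)
  lms <- scene$landmarks
  frame <- build_isb_frame(lms$head_center, lms$epicondyle_medial,
                           lms$epicondyle_lateral, side = "right")
  bm <- bone_metrics(coherent, frame)
  fm <- measure_femur(coherent, lms, frame = frame)
  bone_row <- data.frame(specimen = specimen_id, bone = "femur",
                         volume_mm3 = bm$volume, sa_mm2 = bm$surface_area,
                         cogx = bm$center_of_gravity[1],
                         cogy = bm$center_of_gravity[2],
                         cogz = bm$center_of_gravity[3])
  fem_row <- data.frame(specimen = specimen_id, ma = fm$MA, tea = fm$TEA,
                        fhd = fm$FHD, sd = fm$SD)
  att_rows <- NULL
  if (length(ref$paints)) {
    roles <- vapply(scene$patches, `[[`, character(1), "role")
    fps <- trace_footprints(coherent, ref$paints,
                            epsilon = config$trace_epsilon, roles = roles)
    att_rows <- do.call(rbind, lapply(fps, function(fp) {
      ctr <- to_frame(fp$centroid, frame)
      bt <- to_frame(fp$breakthrough_point, frame)
      data.frame(specimen = specimen_id, attachment = fp$attachment_name,
                 role = fp$attachment_role, bone = "femur",
                 area_mm2 = fp$area, cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 bx = bt[1], by = bt[2], bz = bt[3],
                 fallback = fp$fallback)
    }))
  }
  list(deviations = do.call(rbind, dev_rows), bones = bone_row,
       femoral = fem_row, attachments = att_rows, warnings = warnings)
}

#' Run the full reconstruction pipeline on a synthetic cohort
#'
#' For every specimen: emulate repeat CT scans with inter-scan
#' repositioning and noise, segment bone and paint by HU thresholds,
#' reconstruct surfaces, register repeat scans to the scan-1 reference and
#' quantify deviation, build the coherent model and ISB frame, measure bone
#' and femoral morphometrics, trace footprints and express centroids and
#' breakthrough points in the anatomical frame.  A failure in one specimen
#' is recorded in the manifest and does not abort the others.
#'
#' @param cohort result of [make_cohort()]; generated from `config$seed`
#'   when `NULL`.
#' @param config a `PipelineConfig`.
#' @param out_dir output directory for report CSVs and the manifest
#'   (created if missing); `NULL` to skip writing.
#' @return list with `deviations`, `bones`, `femoral`, `attachments`
#'   (per-specimen data frames), `tables` (a `CohortTable`) and `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- make_cohort(seed = config$seed)
  res <- list(deviations = NULL, bones = NULL, femoral = NULL,
              attachments = NULL)
  errors <- character(0); warnings <- character(0)
  for (i in seq_along(cohort$scenes)) {
    out <- tryCatch(
      withCallingHandlers(
        .analyze_specimen(cohort$scenes[[i]], config, i),
        warning = function(w) {
          warnings <<- c(warnings, paste0("specimen ", i, ": ",
                                          conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(out, "error")) {
      errors <- c(errors, paste0("specimen ", i, ": ", conditionMessage(out)))
      next
    }
    warnings <- c(warnings, out$warnings)
    for (nm in c("deviations", "bones", "femoral", "attachments"))
      if (!is.null(out[[nm]]))
        res[[nm]] <- rbind(res[[nm]], out[[nm]])
  }
  tables <- render_tables(deviations = res$deviations, bones = res$bones,
                          femoral = res$femoral,
                          attachments = res$attachments)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctfootprint")),
    config = unclass(config),
    n_specimens = length(cohort$scenes),
    n_errors = length(errors), errors = errors,
    n_warnings = length(warnings), warnings = warnings,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
    wr(res$deviations, "deviations.csv")
    wr(res$bones, "bone_metrics.csv")
    wr(res$femoral, "femoral_parameters.csv")
    wr(res$attachments, "attachments.csv")
    for (nm in names(tables))
      utils::write.csv(tables[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  c(res, list(tables = tables, manifest = manifest))
}
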
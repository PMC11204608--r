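# File formats: STL (ASCII and binary), PLY (ASCII), NIfTI volumes via
# RNifti, landmark and transform JSON.

#' Write a mesh to STL
#'
#' @param mesh a `TriangleMesh`.
#' @param path output file.
#' @param binary write the 80-byte-header binary dialect (default); ASCII
#'   otherwise.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid ctfootprint", con)
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
    for (i in seq_len(nrow(f))) {
      writeLines(c(paste("facet normal", fmt(n[i, ])),
                   "  outer loop",
                   paste("    vertex", fmt(v[f[i, 1], ])),
                   paste("    vertex", fmt(v[f[i, 2], ])),
                   paste("    vertex", fmt(v[f[i, 3], ])),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid ctfootprint", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII, auto-detected)
#'
#' Duplicate corner vertices are welded so shared topology is restored.
#'
#' @param path STL file.
#' @param weld_tol welding tolerance in mm.
#' @return a `TriangleMesh`.
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path)
  if (sz < 15) stop("not an STL file (truncated at byte ", sz, "): ", path)
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84, sz))
  close(con)
  is_bin <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (sz == 84 + 50 * as.numeric(ntri)) is_bin <- TRUE
  }
  if (!is_bin && !grepl("^\\s*solid", rawToChar(head84[1:min(20, sz)])))
    stop("unrecognized STL header at byte 0: ", path)
  if (is_bin) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    vs <- matrix(NA_real_, 3 * ntri, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      vs[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vl) %% 3 != 0)
      stop("malformed ASCII STL (vertex count not divisible by 3, line ",
           length(vl), "): ", path)
    parts <- strsplit(trimws(vl), "\\s+")
    vs <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  }
  if (any(!is.finite(vs))) stop("non-finite vertex data in ", path)
  f <- matrix(seq_len(nrow(vs)), ncol = 3, byrow = TRUE)
  weld_vertices(triangle_mesh(vs, f), tol = weld_tol)
}

#' Write a mesh to ASCII PLY, optionally with a per-face label channel
#'
#' @param mesh a `TriangleMesh`.
#' @param path output file.
#' @param face_labels optional integer vector (one per face) written as a
#'   `label` face property.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, face_labels = NULL) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices")
  if (!is.null(face_labels)) {
    stopifnot(length(face_labels) == nrow(f))
    hdr <- c(hdr, "property int label")
  }
  hdr <- c(hdr, "end_header")
  body_v <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  body_f <- if (is.null(face_labels))
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  else
    sprintf("3 %d %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L,
            as.integer(face_labels))
  writeLines(c(hdr, body_v, body_f), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path PLY file.
#' @return a `TriangleMesh`; face labels (if present) in attribute
#'   `face_labels`.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || txt[1] != "ply") stop("not a PLY file (line 1): ", path)
  end <- match("end_header", txt)
  if (is.na(end)) stop("malformed PLY: no end_header: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)))
  has_label <- any(grepl("^property int label", txt[seq_len(end)]))
  vl <- txt[(end + 1):(end + nv)]
  fl <- txt[(end + nv + 1):(end + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[1:3])))
  fparts <- strsplit(fl, "\\s+")
  f <- do.call(rbind, lapply(fparts, function(p) as.integer(p[2:4]) + 1L))
  mesh <- triangle_mesh(v, f)
  if (has_label)
    attr(mesh, "face_labels") <-
      vapply(fparts, function(p) as.integer(p[5]), integer(1))
  mesh
}

#' Write / read a CT volume as NIfTI
#'
#' Spacing is stored in the NIfTI `pixdim` header; the origin in the sform
#' translation.
#'
#' @param volume a `CTVolume`.
#' @param path `.nii` or `.nii.gz` file.
#' @return `read_volume` returns a `CTVolume`.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "CTVolume")) stop("expected a CTVolume")
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$values,
                         reference = list(pixdim = c(1, volume$spacing, 1, 1, 1, 1)))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  aff <- RNifti::xform(img)
  ct_volume(array(as.numeric(img), dim(img)),
            spacing = abs(diag(aff)[1:3]),
            origin = aff[1:3, 4])
}

#' Landmark and transform JSON
#'
#' Landmarks are stored as `{name: [x, y, z]}` (mm); transforms as row-major
#' 4x4 homogeneous matrices.
#'
#' @param landmarks named list of length-3 numeric vectors.
#' @param transform a `RigidTransform`.
#' @param path file path.
#' @return readers return the parsed object.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.numeric)
}

#' @rdname write_landmarks
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(as.numeric(t(m)), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(x), 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
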
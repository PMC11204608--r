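# HU-window thresholding and isosurface reconstruction of bone and paint.

#' Construct a CT volume object
#'
#' @param values 3D numeric array of Hounsfield units.
#' @param spacing voxel spacing, scalar or length-3 (mm).
#' @param origin world coordinate of the centre of voxel `[1,1,1]` (mm).
#' @return an object of class `CTVolume`.
#' @export
ct_volume <- function(values, spacing = 1.0, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  sp <- rep(as.numeric(spacing), length.out = 3)
  if (any(sp <= 0)) stop("spacing must be positive")
  if (!all(is.finite(values))) stop("HU values must be finite")
  structure(list(values = values, spacing = sp, origin = as.numeric(origin)),
            class = "CTVolume")
}

#' Threshold a CT volume by an HU window
#'
#' Marks voxels inside the inclusive window `[hu_min, hu_max]`.  The default
#' window is the conventional primary bone window, 250 to 3000 HU.
#'
#' @param volume a `CTVolume`.
#' @param hu_min,hu_max window bounds in HU (inclusive).
#' @return an object of class `LabelMask` (logical 3D grid plus the source
#'   geometry and a `label`).
#' @export
threshold_segment <- function(volume, hu_min = 250, hu_max = 3000) {
  if (!inherits(volume, "CTVolume")) stop("expected a CTVolume")
  if (hu_min >= hu_max) stop("hu_min must be below hu_max")
  m <- volume$values >= hu_min & volume$values <= hu_max
  if (!any(m)) warning("threshold window selects no voxels")
  structure(list(values = m, spacing = volume$spacing, origin = volume$origin,
                 label = "bone"), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask '%s': %s voxels, %d set\n", x$label,
              paste(dim(x$values), collapse = " x "), sum(x$values)))
  invisible(x)
}

# binary dilation by one voxel (26-neighbourhood), zero padded
.dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    tx <- sx + dx; ty <- sy + dy; tz <- sz + dz
    ok <- list(tx >= 1 & tx <= d[1], ty >= 1 & ty <= d[2], tz >= 1 & tz <= d[3])
    out[sx[ok[[1]]], sy[ok[[2]]], sz[ok[[3]]]] <-
      out[sx[ok[[1]]], sy[ok[[2]]], sz[ok[[3]]]] |
      m[tx[ok[[1]]], ty[ok[[2]]], tz[ok[[3]]]]
  }
  out
}

#' Separate paint from bone inside a primary mask
#'
#' Voxels at or above `paint_hu_min` within the primary mask seed the paint
#' label; the seed is dilated by one voxel (26-neighbourhood) and
#' re-intersected with the primary mask to capture the paint/bone
#' interblending rim.  Bone is the remainder of the primary mask, so the two
#' labels always partition it.
#'
#' @param volume a `CTVolume`.
#' @param bone_mask the primary `LabelMask` from [threshold_segment()].
#' @param paint_hu_min secondary threshold (HU), default 2000.
#' @return list with elements `bone` and `paint`, both `LabelMask`.
#' @export
split_paint <- function(volume, bone_mask, paint_hu_min = 2000) {
  if (!inherits(bone_mask, "LabelMask")) stop("expected a LabelMask")
  if (!identical(dim(volume$values), dim(bone_mask$values)))
    stop("volume and mask shapes differ")
  seed <- volume$values >= paint_hu_min & bone_mask$values
  paint <- .dilate1(seed) & bone_mask$values
  bone <- bone_mask$values & !paint
  list(bone = structure(list(values = bone, spacing = bone_mask$spacing,
                             origin = bone_mask$origin, label = "bone"),
                        class = "LabelMask"),
       paint = structure(list(values = paint, spacing = bone_mask$spacing,
                              origin = bone_mask$origin, label = "paint"),
                         class = "LabelMask"))
}

#' Voxel volume of a mask (mm^3)
#' @param mask a `LabelMask`.
#' @export
mask_volume <- function(mask) sum(mask$values) * prod(mask$spacing)

#' Extract a triangulated surface from a binary mask
#'
#' The 0.5-level isosurface of the binary grid is extracted by marching
#' tetrahedra after padding with outside values, scaled by the voxel spacing
#' and shifted by the volume origin.  `field_smoothing` box-filter passes on
#' the indicator (default one) remove most of the surface-area bias that
#' midpoint isosurfaces of binary grids carry; use 0 to reproduce the raw
#' binary isosurface (required for structures only one voxel thick, such as
#' paint shells, which a smoothing pass would erase).
#'
#' @param mask a `LabelMask`.
#' @param keep `"largest_component"` (default) or `"all"`.
#' @param field_smoothing number of box-smoothing passes (0 = none).
#' @return a consistently oriented `TriangleMesh` in mm.
#' @export
extract_surface <- function(mask, keep = c("largest_component", "all"),
                            field_smoothing = 1L) {
  keep <- match.arg(keep)
  if (!inherits(mask, "LabelMask")) stop("expected a LabelMask")
  if (!any(mask$values)) stop("cannot extract a surface from an empty mask")
  field <- array(as.numeric(mask$values), dim(mask$values))
  if (field_smoothing > 0) {
    sm <- smooth_field3(field, field_smoothing)
    # never let smoothing erase thin structures entirely
    if (any(sm >= 0.5)) field <- sm
  }
  mesh <- mesh_from_field(field, spacing = mask$spacing, origin = mask$origin,
                          level = 0.5)
  if (keep == "largest_component") {
    comp <- mesh_components(mesh)
    ar <- face_areas(mesh)
    best <- which.max(tapply(ar, comp, sum))
    mesh <- submesh(mesh, which(comp == as.integer(names(best))))
  }
  mesh
}
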
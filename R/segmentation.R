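#' Threshold plan
#'
#' A global segmentation threshold plus optional per-slice absolute
#' replacements, supporting threshold adjustment on an image-by-image
#' (slice-by-slice) basis when the global threshold fails locally.
#'
#' @param global_value Global intensity threshold.
#' @param overrides Named numeric vector of absolute per-slice thresholds;
#'   names are 0-based slice indices. May be empty.
#' @return Object of class `threshold_plan`.
#' @export
threshold_plan <- function(global_value, overrides = numeric()) {
  if (!is.numeric(global_value) || length(global_value) != 1L ||
      !is.finite(global_value))
    stop("global_value must be a single finite number", call. = FALSE)
  overrides <- unlist(overrides)
  if (length(overrides)) {
    if (!is.numeric(overrides) || any(!is.finite(overrides)))
      stop("override thresholds must be finite numbers", call. = FALSE)
    idx <- suppressWarnings(as.integer(names(overrides)))
    if (is.null(names(overrides)) || anyNA(idx) || any(idx < 0))
      stop("overrides must be named by 0-based slice index", call. = FALSE)
  }
  structure(list(global_value = global_value, overrides = overrides),
            class = "threshold_plan")
}

check_roi_in_image <- function(image, roi) {
  d <- dim(image$data)
  if (roi$slice > d[1] - 1L)
    stop(sprintf("ROI slice %d out of range (image has %d slices)",
                 roi$slice, d[1]), call. = FALSE)
  if (any(roi$vertices[, 1] < -0.5) || any(roi$vertices[, 1] > d[2] - 0.5) ||
      any(roi$vertices[, 2] < -0.5) || any(roi$vertices[, 2] > d[3] - 0.5))
    stop("polygon vertices lie outside the image bounds", call. = FALSE)
  invisible(TRUE)
}

#' Estimate a segmentation threshold from a reference ROI
#'
#' Returns the arithmetic mean intensity over the voxels of one slice whose
#' centres fall within a manually outlined polygon. When the ROI contains
#' approximately equal amounts of tumour and background tissue, this mean
#' sits midway between the two class intensities and serves as the global
#' segmentation threshold.
#'
#' @param image An [image_volume].
#' @param roi A [planar_roi] straddling the tumour border.
#' @return Mean intensity (scalar). Voxel centres lying exactly on the
#'   polygon edge are part of the outlined region and are included.
#' @export
estimate_threshold <- function(image, roi) {
  stopifnot(inherits(image, "image_volume"), inherits(roi, "planar_roi"))
  check_roi_in_image(image, roi)
  d <- dim(image$data)
  sel <- polygon_voxels(roi$vertices, d[2], d[3])
  pick <- sel$inside | sel$boundary
  if (!any(pick)) stop("empty ROI: polygon covers no voxel centres", call. = FALSE)
  mean(image$data[roi$slice + 1L, , ][pick])
}

#' Apply a threshold plan to an image
#'
#' Labels a voxel tumour iff its intensity is greater than or equal to the
#' effective threshold of its slice (the per-slice override when present,
#' else the global value). Tumours are hyperintense on T2-weighted images,
#' hence the `>=` direction; ties go to tumour.
#'
#' @param image An [image_volume].
#' @param plan A [threshold_plan].
#' @return A [seg_mask] with a `threshold` provenance record.
#' @export
apply_threshold <- function(image, plan) {
  stopifnot(inherits(image, "image_volume"), inherits(plan, "threshold_plan"))
  d <- dim(image$data)
  thr <- rep(plan$global_value, d[1])
  if (length(plan$overrides)) {
    idx <- as.integer(names(plan$overrides))
    if (any(idx > d[1] - 1L))
      stop("override slice index out of range", call. = FALSE)
    thr[idx + 1L] <- plan$overrides
  }
  labels <- array(as.vector(image$data) >= rep(thr, times = d[2] * d[3]), dim = d)
  seg_mask(labels, list(list(op = "threshold",
                             global_value = plan$global_value,
                             overrides = as.list(plan$overrides))))
}

#' Exclude polygon-delineated regions from a mask
#'
#' Sets to background, on each polygon's slice, every voxel selected by the
#' polygon. Selection is by voxel-centre test; voxels whose centres lie
#' exactly on the polygon edge follow `boundary_policy`: under the default
#' `"background"` they are excluded too, under `"tumour"` they keep their
#' current label. The assignment of rim voxels is consequential because the
#' over/under volume errors it induces are asymmetric (see the
#' partial-volume simulator).
#'
#' @param mask A [seg_mask].
#' @param polygons List of [planar_roi] exclusion polygons (possibly empty).
#' @param boundary_policy `"background"` (default) or `"tumour"`.
#' @return The modified [seg_mask]; exclusion never increases voxel count.
#' @export
exclude_polygons <- function(mask, polygons,
                             boundary_policy = c("background", "tumour")) {
  stopifnot(inherits(mask, "seg_mask"))
  boundary_policy <- match.arg(boundary_policy)
  if (inherits(polygons, "planar_roi")) polygons <- list(polygons)
  d <- dim(mask$labels)
  for (roi in polygons) {
    stopifnot(inherits(roi, "planar_roi"))
    if (roi$slice > d[1] - 1L)
      stop(sprintf("exclusion polygon on out-of-range slice %d", roi$slice),
           call. = FALSE)
    sel <- polygon_voxels(roi$vertices, d[2], d[3])
    drop <- sel$inside
    if (boundary_policy == "background") drop <- drop | sel$boundary
    sl <- mask$labels[roi$slice + 1L, , ]
    sl[drop] <- FALSE
    mask$labels[roi$slice + 1L, , ] <- sl
    mask <- append_provenance(mask, list(op = "exclude_polygon",
                                         slice = roi$slice,
                                         n_vertices = nrow(roi$vertices),
                                         boundary_policy = boundary_policy))
  }
  mask
}

# Shift a logical 3D array by one voxel along an axis, padding with FALSE.
shift_bool <- function(a, axis, dir) {
  d <- dim(a)
  b <- array(FALSE, d)
  n <- d[axis]
  if (n == 1L) return(b)
  src <- if (dir > 0) 1:(n - 1L) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1L)
  switch(axis,
         b[dst, , ] <- a[src, , ],
         b[, dst, ] <- a[, src, ],
         b[, , dst] <- a[, , src])
  b
}

neighbour_any <- function(a, axes) {
  out <- array(FALSE, dim(a))
  for (ax in axes) for (dir in c(-1L, 1L)) out <- out | shift_bool(a, ax, dir)
  out
}

# Grow `start` through `domain` to a fixed point under face connectivity on
# the given axes (axes 1:3 = 6-connectivity in 3D; axes 2:3 = independent
# 4-connectivity within each slice).
flood_region <- function(domain, start, axes) {
  reach <- start & domain
  repeat {
    grown <- domain & (reach | neighbour_any(reach, axes))
    if (!any(grown & !reach)) break
    reach <- grown
  }
  reach
}

border_voxels <- function(d, axes) {
  b <- array(FALSE, d)
  for (ax in axes) {
    switch(ax,
           { b[1L, , ] <- TRUE; b[d[1], , ] <- TRUE },
           { b[, 1L, ] <- TRUE; b[, d[2], ] <- TRUE },
           { b[, , 1L] <- TRUE; b[, , d[3]] <- TRUE })
  }
  b
}

#' Convert enclosed background regions to tumour (growing seed)
#'
#' Regions of low intra-tumour signal (e.g. necrosis) fall below the
#' threshold and are erroneously assigned to background; this operation
#' relabels them as tumour. In automatic mode (no seeds) every connected
#' background component that is not connected to the image border is
#' converted (hole filling). In seeded mode only enclosed components
#' containing a seed are converted; a seed already inside tumour, or in a
#' component connected to the image border, triggers a warning and no
#' change.
#'
#' Connectivity is face connectivity: `"3d6"` (6-neighbourhood in 3D,
#' default) or `"2d4"` (4-neighbourhood independently per slice, the
#' conservative choice for thick-slice 2D stacks).
#'
#' @param mask A [seg_mask].
#' @param seeds Optional matrix (or list) of 0-based `(slice, row, column)`
#'   voxel coordinates.
#' @param connectivity `"3d6"` or `"2d4"`.
#' @return The filled [seg_mask]; filling never decreases voxel count and is
#'   idempotent.
#' @export
fill_interior <- function(mask, seeds = NULL, connectivity = c("3d6", "2d4")) {
  stopifnot(inherits(mask, "seg_mask"))
  connectivity <- match.arg(connectivity)
  axes <- if (connectivity == "3d6") 1:3 else 2:3
  d <- dim(mask$labels)
  bg <- !mask$labels
  outer_bg <- flood_region(bg, border_voxels(d, axes), axes)
  if (is.null(seeds)) {
    holes <- bg & !outer_bg
  } else {
    if (is.list(seeds)) seeds <- do.call(rbind, lapply(seeds, as.numeric))
    seeds <- matrix(as.numeric(seeds), ncol = 3L)
    holes <- array(FALSE, d)
    for (k in seq_len(nrow(seeds))) {
      s <- seeds[k, ]
      if (any(s != floor(s)) || any(s < 0) || any(s > d - 1L))
        stop("seed out of bounds", call. = FALSE)
      i <- as.integer(s) + 1L
      if (mask$labels[i[1], i[2], i[3]]) {
        warning(sprintf("seed (%d,%d,%d) lies inside the tumour region; ignored",
                        i[1] - 1L, i[2] - 1L, i[3] - 1L))
        next
      }
      if (outer_bg[i[1], i[2], i[3]]) {
        warning(sprintf(
          "seed (%d,%d,%d) is in background connected to the image border; not filled",
          i[1] - 1L, i[2] - 1L, i[3] - 1L))
        next
      }
      start <- array(FALSE, d)
      start[i[1], i[2], i[3]] <- TRUE
      holes <- holes | flood_region(bg, start, axes)
    }
  }
  mask$labels <- mask$labels | holes
  append_provenance(mask, list(op = "fill_interior",
                               mode = if (is.null(seeds)) "auto" else "seeded",
                               connectivity = connectivity,
                               n_filled = sum(holes)))
}

#' Full semi-automatic tumour segmentation pipeline
#'
#' Composes the delineation stages in their canonical order: ROI-derived
#' global threshold, per-slice threshold overrides, thresholding, polygon
#' exclusion of failed regions, growing-seed conversion of enclosed
#' low-signal interior, and voxel-count to mass conversion. The returned
#' mask carries the full provenance of every stage.
#'
#' @param image An [image_volume].
#' @param roi A [planar_roi] over roughly equal amounts of tumour and
#'   background, used to derive the global threshold.
#' @param overrides Named numeric vector of absolute per-slice thresholds
#'   (names = 0-based slice indices).
#' @param polygons List of exclusion [planar_roi]s.
#' @param seeds Optional seed coordinates for [fill_interior]; `NULL` fills
#'   all enclosed holes automatically.
#' @param density_g_cm3 Assumed tumour density.
#' @param boundary_policy Rim-voxel policy for [exclude_polygons].
#' @param connectivity `"auto"` (default: per-slice 4-connectivity when the
#'   slice spacing is at least twice the in-plane spacing, else 3D
#'   6-connectivity), `"3d6"`, or `"2d4"`.
#' @return List with elements `mask` (a [seg_mask]), `mass` (a
#'   [mass_estimate]) and `threshold` (the derived global threshold).
#' @export
segment_tumour <- function(image, roi, overrides = numeric(), polygons = list(),
                           seeds = NULL, density_g_cm3 = 1.0,
                           boundary_policy = c("background", "tumour"),
                           connectivity = c("auto", "3d6", "2d4")) {
  connectivity <- match.arg(connectivity)
  boundary_policy <- match.arg(boundary_policy)
  if (connectivity == "auto") {
    connectivity <- if (image$spacing_um[1] >= 2 * max(image$spacing_um[2:3]))
      "2d4" else "3d6"
  }
  thr <- estimate_threshold(image, roi)
  plan <- threshold_plan(thr, overrides)
  mask <- apply_threshold(image, plan)
  mask <- exclude_polygons(mask, polygons, boundary_policy)
  mask <- fill_interior(mask, seeds, connectivity)
  mass <- mask_to_mass(mask, image$spacing_um, density_g_cm3)
  list(mask = mask, mass = mass, threshold = thr)
}
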
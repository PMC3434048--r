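#' Physical voxel volume
#'
#' Volume of a single voxel given its per-axis edge lengths in micrometres.
#' All physical bookkeeping in this package is fixed to one set of units:
#' voxel spacing in um, volumes in mm^3, masses in g, densities in g/cm^3.
#'
#' @param spacing_um Numeric length-3 vector of voxel edge lengths in um,
#'   in `(slice, row, column)` order.
#' @return Voxel volume in mm^3.
#' @examples
#' voxel_volume(c(160, 160, 160))   # 0.004096 mm^3
#' voxel_volume(c(150, 200, 700))   # 0.021 mm^3, a thick-slice 2D protocol
#' @export
voxel_volume <- function(spacing_um) {
  check_spacing(spacing_um)
  prod(spacing_um) / 1e9
}

check_spacing <- function(spacing_um) {
  if (!is.numeric(spacing_um) || length(spacing_um) != 3L ||
      anyNA(spacing_um) || any(!is.finite(spacing_um)) || any(spacing_um <= 0)) {
    stop("invalid spacing: need three finite, strictly positive edge lengths (um)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Image volume with physical voxel spacing
#'
#' Container for a 3D scalar MR image. Axis order is `(slice, row, column)`;
#' `spacing_um` is stored in the same order. Anisotropic multi-slice ("2D")
#' stacks and isotropic 3D volumes share this representation: a 2D protocol
#' is simply a volume whose slice spacing greatly exceeds the in-plane
#' spacing (e.g. 700 um slices over ~150 x 200 um pixels).
#'
#' @param data 3D numeric array of intensities (finite, arbitrary units).
#'   A matrix is promoted to a single-slice volume.
#' @param spacing_um Numeric length-3: voxel edge lengths in um,
#'   `(slice, row, column)` order.
#' @return An object of class `image_volume` with elements `data` and
#'   `spacing_um`.
#' @export
image_volume <- function(data, spacing_um) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (slice, row, column)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("each axis needs at least one voxel", call. = FALSE)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("intensities must be finite numbers", call. = FALSE)
  check_spacing(spacing_um)
  structure(list(data = data, spacing_um = as.numeric(spacing_um)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (slice, row, col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %g x %g x %g um (voxel volume %.6g mm^3)\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
              voxel_volume(x$spacing_um)))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' A tumour/background labelling aligned voxel-for-voxel with its source
#' image (`TRUE` = tumour), together with the ordered provenance of the
#' operations that produced it.
#'
#' @param labels 3D logical array (`TRUE` = tumour).
#' @param provenance List of operation records (each a named list with at
#'   least an `op` element), oldest first.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, provenance = list()) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(1L, dim(labels)))
  if (!is.array(labels) || length(dim(labels)) != 3L || !is.logical(labels))
    stop("labels must be a 3D logical array", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  structure(list(labels = labels, provenance = provenance), class = "seg_mask")
}

append_provenance <- function(mask, record) {
  mask$provenance <- c(mask$provenance, list(record))
  mask
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<seg_mask> %d x %d x %d, %d tumour voxels\n",
              d[1], d[2], d[3], sum(x$labels)))
  ops <- vapply(x$provenance, function(p) p$op, character(1))
  if (length(ops)) cat("  provenance:", paste(ops, collapse = " -> "), "\n")
  invisible(x)
}

#' Mass estimate with provenance
#'
#' @param volume_mm3 Tumour volume in mm^3.
#' @param density_g_cm3 Assumed tissue density in g/cm^3.
#' @param method One of `"seg2D"`, `"seg3D"`, `"gauge_block"`, `"reference"`.
#' @return Object of class `mass_estimate` with elements `mass_g`,
#'   `volume_mm3`, `density_g_cm3`, `method`. Mass is
#'   `volume[cm^3] * density`.
#' @export
mass_estimate <- function(volume_mm3, density_g_cm3 = 1.0,
                          method = c("seg3D", "seg2D", "gauge_block", "reference")) {
  method <- match.arg(method)
  if (!is.numeric(volume_mm3) || length(volume_mm3) != 1L ||
      !is.finite(volume_mm3) || volume_mm3 < 0)
    stop("volume must be a single finite nonnegative number (mm^3)", call. = FALSE)
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1L ||
      !is.finite(density_g_cm3) || density_g_cm3 <= 0)
    stop("invalid density: must be a single positive number (g/cm^3)", call. = FALSE)
  structure(list(mass_g = volume_mm3 / 1000 * density_g_cm3,
                 volume_mm3 = volume_mm3,
                 density_g_cm3 = density_g_cm3,
                 method = method),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("<mass_estimate> %.6g g (%.6g mm^3 at %.3g g/cm^3, method %s)\n",
              x$mass_g, x$volume_mm3, x$density_g_cm3, x$method))
  invisible(x)
}

#' Convert a segmentation mask to a tumour mass
#'
#' The number of tumour voxels, multiplied by the voxel volume, converted to
#' mass under an assumed tissue density (default 1.0 g/cm^3).
#'
#' @param mask A [seg_mask].
#' @param spacing_um Voxel edge lengths in um for the image the mask belongs
#'   to, `(slice, row, column)` order.
#' @param density_g_cm3 Assumed density, g/cm^3.
#' @param method Method tag. Default `"auto"` labels the estimate `"seg2D"`
#'   when the slice spacing is at least twice the largest in-plane spacing
#'   (a thick-slice stack) and `"seg3D"` otherwise.
#' @return A [mass_estimate].
#' @examples
#' m <- seg_mask(array(TRUE, c(10, 10, 10)))
#' mask_to_mass(m, c(160, 160, 160))  # 1000 voxels -> 0.004096 g
#' @export
mask_to_mass <- function(mask, spacing_um, density_g_cm3 = 1.0,
                         method = c("auto", "seg2D", "seg3D")) {
  stopifnot(inherits(mask, "seg_mask"))
  check_spacing(spacing_um)
  method <- match.arg(method)
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1L ||
      !is.finite(density_g_cm3) || density_g_cm3 <= 0)
    stop("invalid density: must be a single positive number (g/cm^3)", call. = FALSE)
  if (method == "auto") {
    method <- if (spacing_um[1] >= 2 * max(spacing_um[2:3])) "seg2D" else "seg3D"
  }
  mass_estimate(sum(mask$labels) * voxel_volume(spacing_um),
                density_g_cm3, method = method)
}
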
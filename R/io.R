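#' Read an MR image volume from NIfTI or multi-page TIFF
#'
#' NIfTI-1 files carry their voxel spacing in the header (`pixdim`, mm);
#' it is converted to um on load. TIFF carries no reliable physical
#' spacing, so `spacing_um` must be supplied for TIFF input. On load the
#' array is reordered into this package's `(slice, row, column)` axis
#' convention: the NIfTI third dimension becomes the slice axis.
#'
#' @param path Path to a `.nii`/`.nii.gz` or `.tif`/`.tiff` file.
#' @param spacing_um Voxel spacing (um) in `(slice, row, column)` order;
#'   required for TIFF, overrides the header when given for NIfTI.
#' @return An [image_volume].
#' @export
read_image_volume <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(spacing_um))
      stop("spacing_um is required for TIFF input (TIFF has no physical spacing)",
           call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1:2]))
    for (i in seq_along(pages)) arr[i, , ] <- as.matrix(pages[[i]])
    return(image_volume(arr, spacing_um))
  }
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  if (is.null(spacing_um)) {
    pd <- RNifti::pixdim(nii)
    spacing_um <- pd[c(3, 2, 1)] * 1000    # mm -> um, slice axis first
  }
  image_volume(aperm(arr, c(3, 2, 1)), spacing_um)
}

#' Write an image volume or mask as NIfTI-1
#'
#' Inverts the axis reordering of [read_image_volume] (slice axis back to
#' the NIfTI third dimension) and stores the spacing in mm in the header.
#' Masks are written with a 0/1 integer payload.
#'
#' @param x An [image_volume] or [seg_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing_um Required for a [seg_mask] (masks do not carry
#'   spacing); ignored for an [image_volume].
#' @return The path, invisibly.
#' @export
write_image_volume <- function(x, path, spacing_um = NULL) {
  if (inherits(x, "image_volume")) {
    arr <- x$data
    spacing_um <- x$spacing_um
  } else if (inherits(x, "seg_mask")) {
    if (is.null(spacing_um))
      stop("spacing_um is required when writing a seg_mask", call. = FALSE)
    check_spacing(spacing_um)
    arr <- array(as.integer(x$labels), dim(x$labels))
  } else {
    stop("x must be an image_volume or a seg_mask", call. = FALSE)
  }
  out <- aperm(arr, c(3, 2, 1))
  nii <- RNifti::asNifti(out)
  RNifti::pixdim(nii) <- spacing_um[c(3, 2, 1)] / 1000
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_image_volume
#' @export
write_seg_mask <- function(x, path, spacing_um) {
  stopifnot(inherits(x, "seg_mask"))
  write_image_volume(x, path, spacing_um)
}

#' Write a run-provenance JSON sidecar
#'
#' Every artifact-producing command records its inputs, parameters, seed
#' and software version, sufficient to replay the run bit-identically.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param params Named list of parameters.
#' @param seed Integer seed or `NULL`.
#' @param extra Optional named list (e.g. per-stage voxel counts).
#' @return The path, invisibly.
#' @export
write_provenance <- function(path, command, params, seed = NULL, extra = list()) {
  payload <- c(list(command = command,
                    package = "tumourvol",
                    version = as.character(utils::packageVersion("tumourvol")),
                    seed = seed,
                    params = params),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
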
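# Shared in-code fixtures: tiny two-class images, ring masks, square ROIs.

# Two-valued volume: a centred axis-aligned box of `tumour` intensity on a
# `background` field. Returns the image and the ground-truth logical array.
two_class_volume <- function(dim = c(5L, 12L, 12L), box_lo = c(2L, 4L, 4L),
                             box_hi = c(4L, 9L, 9L), tumour = 100,
                             background = 20, spacing_um = c(160, 160, 160)) {
  arr <- array(background, dim)
  truth <- array(FALSE, dim)
  truth[box_lo[1]:box_hi[1], box_lo[2]:box_hi[2], box_lo[3]:box_hi[3]] <- TRUE
  arr[truth] <- tumour
  list(image = image_volume(arr, spacing_um), truth = truth)
}

# Single-slice annulus (ring) mask: tumour ring with an enclosed hole.
ring_mask <- function(n = 15L, r_outer = 6, r_inner = 3) {
  cc <- seq_len(n) - (n + 1) / 2
  d2 <- outer(cc^2, cc^2, "+")
  ring <- d2 <= r_outer^2 & d2 > r_inner^2
  disk <- d2 <= r_outer^2
  list(mask = seg_mask(array(ring, c(1L, n, n)),
                       list(list(op = "fixture"))),
       disk = array(disk, c(1L, n, n)))
}

# Axis-aligned square ROI with corners on voxel-centre coordinates.
square_roi <- function(slice, lo, hi) {
  planar_roi(slice, rbind(c(lo, lo), c(lo, hi), c(hi, hi), c(hi, lo)))
}

# Brute-force point-in-polygon oracle over all voxel centres of a slice
# (winding-free even-odd count, written independently of the package
# internals; boundary points classified separately by exact comparisons
# for the axis-aligned squares used in tests).
brute_square_selection <- function(nr, nc, lo, hi) {
  rows <- matrix(0:(nr - 1L), nr, nc)
  cols <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  rows >= lo & rows <= hi & cols >= lo & cols <= hi
}
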
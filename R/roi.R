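#' Planar region of interest
#'
#' A closed polygon drawn on one slice, used both for the threshold ROI
#' (outlining roughly equal amounts of tumour and background) and for the
#' exclusion polygons that remove regions of failed segmentation.
#'
#' Coordinates are 0-based voxel coordinates in `(row, column)` order, with
#' the centre of voxel `(i, j)` at exactly `(i, j)`; fractional vertices are
#' allowed. The polygon is closed implicitly (last vertex connects back to
#' the first) and must not self-intersect.
#'
#' @param slice 0-based slice index.
#' @param vertices Numeric matrix with >= 3 rows and 2 columns
#'   `(row, column)`, or a list of length-2 points.
#' @return Object of class `planar_roi`.
#' @export
planar_roi <- function(slice, vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be a numeric matrix with >= 3 rows of (row, col)",
         call. = FALSE)
  if (any(!is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  if (!is.numeric(slice) || length(slice) != 1L || slice != floor(slice) || slice < 0)
    stop("slice must be a single nonnegative integer (0-based)", call. = FALSE)
  validate_simple_polygon(vertices)
  structure(list(slice = as.integer(slice), vertices = unname(vertices)),
            class = "planar_roi")
}

#' @export
print.planar_roi <- function(x, ...) {
  cat(sprintf("<planar_roi> slice %d, %d vertices\n", x$slice, nrow(x$vertices)))
  invisible(x)
}

# Reject zero-length edges and any proper or improper crossing between
# non-adjacent edges (collinear overlap included).
validate_simple_polygon <- function(v) {
  n <- nrow(v)
  e1 <- v
  e2 <- v[c(2:n, 1L), , drop = FALSE]
  len2 <- rowSums((e2 - e1)^2)
  if (any(len2 == 0)) stop("polygon has a zero-length edge", call. = FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(e1[i, ], e2[i, ], e1[j, ], e2[j, ]))
        stop("polygon is self-intersecting", call. = FALSE)
    }
  }
  invisible(TRUE)
}

orient <- function(a, b, c) {
  (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
}

on_segment_collinear <- function(a, b, p) {
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_segment_collinear(p3, p4, p1)) ||
    (d2 == 0 && on_segment_collinear(p3, p4, p2)) ||
    (d3 == 0 && on_segment_collinear(p1, p2, p3)) ||
    (d4 == 0 && on_segment_collinear(p1, p2, p4))
}

# Rasterize a polygon against the voxel-centre lattice of an nr x nc slice.
# Returns logical matrices `inside` (centre strictly interior, even-odd
# rule) and `boundary` (centre exactly on a polygon edge, within a small
# numeric tolerance).
polygon_voxels <- function(vertices, nr, nc) {
  py <- matrix(0:(nr - 1L), nr, nc)                # rows
  px <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)  # columns
  n <- nrow(vertices)
  eps <- 1e-9 * max(1, max(abs(vertices)))
  crossings <- matrix(0L, nr, nc)
  on_edge <- matrix(FALSE, nr, nc)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- vertices[i, 1]; x1 <- vertices[i, 2]
    y2 <- vertices[j, 1]; x2 <- vertices[j, 2]
    cond <- (y1 > py) != (y2 > py)
    xin <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    hit <- cond & (px < xin)
    hit[is.na(hit)] <- FALSE
    crossings <- crossings + hit
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    cross <- (px - x1) * dy - (py - y1) * dx
    tpar <- ((px - x1) * dx + (py - y1) * dy) / len2
    on_edge <- on_edge |
      (abs(cross) <= eps * sqrt(len2) & tpar >= -eps & tpar <= 1 + eps)
  }
  inside <- (crossings %% 2L == 1L) & !on_edge
  list(inside = inside, boundary = on_edge)
}

#' Read or write planar ROIs as JSON
#'
#' The on-disk schema is a JSON array of objects
#' `{"slice": int, "vertices": [[row, col], ...]}` with 0-based voxel
#' coordinates (voxel centre = integer coordinate). A single object is also
#' accepted on read.
#'
#' @param path File path.
#' @return `read_rois_json()` returns a list of [planar_roi] objects.
#' @export
read_rois_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$slice)) raw <- list(raw)
  lapply(raw, function(r) {
    verts <- do.call(rbind, lapply(r$vertices, function(v) as.numeric(unlist(v))))
    planar_roi(r$slice, verts)
  })
}

#' @param rois List of [planar_roi] objects (or a single one).
#' @rdname read_rois_json
#' @export
write_rois_json <- function(rois, path) {
  if (inherits(rois, "planar_roi")) rois <- list(rois)
  out <- lapply(rois, function(r) list(slice = r$slice, vertices = r$vertices))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
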
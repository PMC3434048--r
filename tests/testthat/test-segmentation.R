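test_that("ROI mean threshold recovers the class midpoint on balanced ROIs", {
  tc <- two_class_volume()
  # square ROI straddling the box edge on slice 2 (0-based): the tumour box
  # covers rows/cols 3..8, so rows 3..8 x cols 1..4 is half tumour, half
  # background (12 voxels each)
  roi <- planar_roi(2, rbind(c(3, 1), c(3, 4), c(8, 4), c(8, 1)))
  expect_equal(estimate_threshold(tc$image, roi), 60)

  # constant region -> identity
  flat <- image_volume(array(42, c(3, 8, 8)), c(160, 160, 160))
  expect_equal(estimate_threshold(flat, square_roi(1, 2, 5)), 42)

  # {100, 100, 40} -> 80: a 1x3 strip at 0-based row 2, cols 1..3
  arr <- array(20, c(1, 5, 5))
  arr[1, 3, 2:4] <- c(100, 100, 40)
  strip <- planar_roi(0, rbind(c(1.6, 0.6), c(1.6, 3.4), c(2.4, 3.4), c(2.4, 0.6)))
  expect_equal(estimate_threshold(image_volume(arr, c(700, 150, 200)), strip), 80)
})

test_that("balanced two-class ROIs yield the exact midpoint over random cases", {
  set.seed(42)
  for (i in 1:20) {
    lo <- sample(10:60, 1)
    hi <- lo + sample(30:100, 1)
    n <- 12L
    arr <- array(lo, c(1L, n, n))
    split_col <- n / 2
    arr[1, , (split_col + 1):n] <- hi   # exactly half the slice high
    img <- image_volume(arr, c(160, 160, 160))
    roi <- square_roi(0, 0, n - 1L)     # covers every voxel centre
    expect_equal(estimate_threshold(img, roi), (lo + hi) / 2)
  }
})

test_that("empty ROI raises an error", {
  img <- image_volume(array(1, c(1, 10, 10)), c(160, 160, 160))
  tiny <- planar_roi(0, rbind(c(2.1, 2.1), c(2.1, 2.4), c(2.4, 2.4)))
  expect_error(estimate_threshold(img, tiny), "empty ROI")
})

test_that("thresholding separates two-valued images exactly", {
  tc <- two_class_volume()
  mask <- apply_threshold(tc$image, threshold_plan(60))
  expect_identical(mask$labels, tc$truth)
  expect_equal(mask$provenance[[1]]$op, "threshold")

  above <- apply_threshold(tc$image, threshold_plan(101))
  expect_false(any(above$labels))
})

test_that("per-slice overrides replace the global threshold on their slice only", {
  tc <- two_class_volume()
  ov <- c("0" = 10)  # below slice 0's minimum -> slice fully tumour
  mask <- apply_threshold(tc$image, threshold_plan(60, ov))
  expect_true(all(mask$labels[1, , ]))
  expect_identical(mask$labels[-1, , ], tc$truth[-1, , ])
  expect_error(apply_threshold(tc$image, threshold_plan(60, c("99" = 1))),
               "out of range")
})

test_that("threshold ties go to tumour (>= comparison)", {
  arr <- array(c(59, 60, 61), c(1, 1, 3))
  mask <- apply_threshold(image_volume(arr, c(1, 1, 1)), threshold_plan(60))
  expect_identical(as.vector(mask$labels), c(FALSE, TRUE, TRUE))
})

test_that("polygon exclusion removes exactly the centre-selected voxels", {
  n <- 10L
  full <- seg_mask(array(TRUE, c(3L, n, n)), list(list(op = "fixture")))

  # square with corners on voxel centres (2,2)-(5,5): under the default
  # boundary policy exactly the 4x4 voxels with centres in [2,5]^2 go
  excl <- exclude_polygons(full, list(square_roi(1, 2, 5)))
  expected <- brute_square_selection(n, n, 2, 5)
  expect_identical(excl$labels[2, , ], !expected)
  expect_true(all(excl$labels[c(1, 3), , ]))
  expect_equal(sum(!excl$labels), 16)

  # boundary_policy = "tumour" keeps edge-centred voxels: only the 2x2 interior goes
  kept <- exclude_polygons(full, list(square_roi(1, 2, 5)), "tumour")
  expect_equal(sum(!kept$labels), 4)
})

test_that("polygon exclusion identities and monotonicity", {
  n <- 10L
  full <- seg_mask(array(TRUE, c(3L, n, n)), list(list(op = "fixture")))
  expect_identical(exclude_polygons(full, list())$labels, full$labels)

  whole <- square_roi(0, -0.5, n - 0.5)
  wiped <- exclude_polygons(full, list(whole))
  expect_false(any(wiped$labels[1, , ]))
  expect_true(all(wiped$labels[-1, , ]))

  set.seed(3)
  rnd <- seg_mask(array(stats::runif(3 * n * n) > 0.4, c(3L, n, n)),
                  list(list(op = "fixture")))
  out <- exclude_polygons(rnd, list(square_roi(2, 1, 4)))
  expect_lte(sum(out$labels), sum(rnd$labels))
})

test_that("exclusion is invariant to vertex order and polygon order", {
  n <- 12L
  set.seed(9)
  m <- seg_mask(array(stats::runif(2 * n * n) > 0.3, c(2L, n, n)),
                list(list(op = "fixture")))
  tri <- planar_roi(0, rbind(c(1.2, 1.1), c(8.7, 2.3), c(4.4, 9.6)))
  tri_rev <- planar_roi(0, tri$vertices[3:1, ])
  expect_identical(exclude_polygons(m, list(tri))$labels,
                   exclude_polygons(m, list(tri_rev))$labels)

  a <- square_roi(1, 1, 3)
  b <- square_roi(1, 6, 9)
  expect_identical(exclude_polygons(m, list(a, b))$labels,
                   exclude_polygons(m, list(b, a))$labels)
})

test_that("self-intersecting polygons are rejected", {
  bow <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  expect_error(planar_roi(0, bow), "self-intersecting")
  expect_error(planar_roi(0, rbind(c(0, 0), c(0, 0), c(1, 1))), "zero-length")
  expect_error(planar_roi(0, rbind(c(0, 0), c(1, 1))), ">= 3 rows")
})

test_that("hole filling converts enclosed background and nothing else", {
  rings <- ring_mask()
  filled <- fill_interior(rings$mask, connectivity = "2d4")
  expect_identical(filled$labels, rings$disk)

  # background touching the border is not a hole
  open <- seg_mask(array(FALSE, c(1L, 8L, 8L)), list(list(op = "fixture")))
  open$labels[1, 3:6, 3:6] <- TRUE
  open$labels[1, 4:5, 4:5] <- FALSE
  open$labels[1, 4, 3] <- FALSE   # breach the ring wall: hole connects out
  out <- fill_interior(open, connectivity = "2d4")
  expect_identical(out$labels, open$labels)

  # idempotence and monotonicity
  again <- fill_interior(filled, connectivity = "2d4")
  expect_identical(again$labels, filled$labels)
  expect_gte(sum(filled$labels), sum(rings$mask$labels))
})

test_that("3D hole filling uses 6-connectivity (no diagonal leaks)", {
  lab <- array(FALSE, c(5, 5, 5))
  lab[2:4, 2:4, 2:4] <- TRUE
  lab[3, 3, 3] <- FALSE        # fully enclosed cavity
  shell <- seg_mask(lab, list(list(op = "fixture")))
  filled <- fill_interior(shell, connectivity = "3d6")
  expect_true(filled$labels[3, 3, 3])
  expect_equal(sum(filled$labels), 27)

  # a cavity connected to the outside only through a face-path is no hole
  lab2 <- lab
  lab2[3, 3, 4] <- FALSE       # corridor through the wall
  leak <- fill_interior(seg_mask(lab2, list(list(op = "fixture"))), connectivity = "3d6")
  expect_false(leak$labels[3, 3, 3])
})

test_that("seeded filling converts only the seeded enclosed component", {
  lab <- array(FALSE, c(1L, 11L, 11L))
  lab[1, 2:10, 2:10] <- TRUE
  lab[1, 4:5, 4:5] <- FALSE    # hole A
  lab[1, 7:8, 7:8] <- FALSE    # hole B
  m <- seg_mask(lab, list(list(op = "fixture")))

  seeded <- fill_interior(m, seeds = rbind(c(0, 3, 3)), connectivity = "2d4")
  expect_true(all(seeded$labels[1, 4:5, 4:5]))
  expect_false(any(seeded$labels[1, 7:8, 7:8]))

  expect_warning(fill_interior(m, seeds = rbind(c(0, 2, 2)), connectivity = "2d4"),
                 "inside the tumour")
  expect_warning(fill_interior(m, seeds = rbind(c(0, 0, 0)), connectivity = "2d4"),
                 "connected to the image border")
  expect_error(fill_interior(m, seeds = rbind(c(0, 50, 0)), connectivity = "2d4"),
               "out of bounds")
})

test_that("the composed pipeline matches its stages and keeps provenance", {
  tc <- two_class_volume()
  roi <- planar_roi(2, rbind(c(3, 1), c(3, 4), c(8, 4), c(8, 1)))
  res <- segment_tumour(tc$image, roi)
  expect_identical(res$mask$labels, tc$truth)
  expect_equal(res$threshold, 60)
  expect_equal(res$mass$mass_g, sum(tc$truth) * 0.004096 / 1000)
  ops <- vapply(res$mask$provenance, function(p) p$op, character(1))
  expect_identical(ops, c("threshold", "fill_interior"))

  # no voxel above threshold -> empty mask, 0 g
  dim_flat <- image_volume(array(10, c(3, 8, 8)), c(160, 160, 160))
  res0 <- segment_tumour(dim_flat, square_roi(1, 1, 6), overrides = c("0" = 99,
                                                                      "1" = 99,
                                                                      "2" = 99))
  expect_false(any(res0$mask$labels))
  expect_equal(res0$mass$mass_g, 0)
})

test_that("pipeline recovers a sphere phantom within its PVE bounds", {
  # noise-free sphere, 28 voxels across, ROI straddling the rim
  d_um <- 28 * 160
  ph <- render_phantom(phantom_spec(rep(d_um / 2, 3), c(160, 160, 160)))
  ctr <- (dim(ph$image$data)[1] + 1) / 2
  rp <- 14  # rim at 14 voxels from centre in-plane
  roi <- planar_roi(ctr - 1,
                    rbind(c(ctr - 1 - 3, ctr - 1 + rp - 2),
                          c(ctr - 1 - 3, ctr - 1 + rp + 2),
                          c(ctr - 1 + 3, ctr - 1 + rp + 2),
                          c(ctr - 1 + 3, ctr - 1 + rp - 2)))
  res <- segment_tumour(ph$image, roi)
  b <- pve_bounds(28)
  err <- 100 * (res$mass$volume_mm3 - ph$analytic_volume_mm3) / ph$analytic_volume_mm3
  expect_gte(err, b["under_pct"])
  expect_lte(err, b["over_pct"])

  # a low-signal core changes nothing: the filled mass still covers the
  # full (core-included) ground-truth volume
  core <- list(center_um = dim(ph$image$data) * 160 / 2, radius_um = d_um / 6)
  ph2 <- render_phantom(phantom_spec(rep(d_um / 2, 3), c(160, 160, 160),
                                     necrotic_cores = list(core)))
  res2 <- segment_tumour(ph2$image, roi)
  err2 <- 100 * (res2$mass$volume_mm3 - ph2$analytic_volume_mm3) / ph2$analytic_volume_mm3
  expect_gte(err2, b["under_pct"])
  expect_lte(err2, b["over_pct"])
})
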
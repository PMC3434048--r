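#' Diameter of a sphere of given mass
#'
#' @param mass_g Mass in grams.
#' @param density_g_cm3 Density, g/cm^3.
#' @return Sphere diameter in um.
#' @export
mass_to_diameter_um <- function(mass_g, density_g_cm3 = 1.0) {
  stopifnot(all(mass_g > 0), density_g_cm3 > 0)
  v_um3 <- mass_g / density_g_cm3 * 1e12     # cm^3 -> um^3
  (6 * v_um3 / pi)^(1 / 3)
}

#' Synthetic tumour phantom specification
#'
#' Generative description of an MR-like image of a hyperintense ellipsoidal
#' tumour on a darker background, with partial-volume edge voxels, optional
#' enclosed low-signal (necrotic) cores, optional Gaussian point-spread
#' blur, and additive noise. The analytic ellipsoid volume
#' `(4*pi/3) a b c` is the primary ground truth.
#'
#' By default the field of view is sized automatically with a 2-voxel
#' margin and odd dimensions, placing the tumour centre exactly at the
#' centre of the middle voxel. This matches the `element_center` origin
#' convention of the partial-volume simulator, so segmented volumes of
#' sphere phantoms are directly comparable with [simulate_pve] bounds.
#'
#' @param semi_axes_um Numeric length-3 ellipsoid semi-axes (um), in
#'   `(slice, row, column)` order. Equal values give a sphere.
#' @param spacing_um Voxel spacing (um), `(slice, row, column)`.
#' @param dim Optional integer length-3 image dimensions; default sized
#'   automatically (odd, tumour centred on a voxel centre).
#' @param center_um Optional physical tumour centre (um); default the FOV
#'   centre.
#' @param tumour_intensity,background_intensity Intensities (arbitrary
#'   units); tumour must exceed background (T2-hyperintense tumour).
#' @param noise_sigma Additive noise standard deviation (intensity units).
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude MR
#'   noise).
#' @param psf_sigma_um Isotropic Gaussian blur sigma (um); 0 disables.
#' @param necrotic_cores List of cores, each a list with `center_um`
#'   (length 3), `radius_um`, and optional `intensity` (default background
#'   intensity). Cores must lie inside the tumour; they alter intensities
#'   only, never the ground-truth volume (the tumour includes its necrotic
#'   interior).
#' @param supersampling Integer >= 1: edge voxels are subdivided into
#'   `supersampling^3` sample points to compute occupancy fractions.
#'   Automatically raised to 8 for very small tumours (fewer than 6 voxels
#'   across the smallest axis).
#' @param seed Optional integer seed; required for reproducible noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes_um, spacing_um, dim = NULL, center_um = NULL,
                         tumour_intensity = 100, background_intensity = 20,
                         noise_sigma = 0, noise_model = c("gaussian", "rician"),
                         psf_sigma_um = 0, necrotic_cores = list(),
                         supersampling = 4L, seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_spacing(spacing_um)
  semi_axes_um <- as.numeric(semi_axes_um)
  if (length(semi_axes_um) == 1L) semi_axes_um <- rep(semi_axes_um, 3L)
  if (length(semi_axes_um) != 3L || any(!is.finite(semi_axes_um)) ||
      any(semi_axes_um <= 0))
    stop("semi_axes_um must be three positive numbers", call. = FALSE)
  if (tumour_intensity <= background_intensity)
    stop("tumour intensity must exceed background intensity", call. = FALSE)
  if (supersampling < 1L) stop("supersampling must be >= 1", call. = FALSE)
  min_across <- min(2 * semi_axes_um / spacing_um)
  if (min_across < 6) supersampling <- max(supersampling, 8L)
  if (is.null(dim)) {
    dim <- 2L * ceiling(semi_axes_um / spacing_um) + 5L   # odd, >= 2-voxel margin
  }
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("dim must be three positive integers",
                                               call. = FALSE)
  if (is.null(center_um)) center_um <- dim * spacing_um / 2
  center_um <- as.numeric(center_um)
  # tumour (plus margin) must fit in the FOV with at least one voxel to spare
  if (any(center_um - semi_axes_um < spacing_um) ||
      any(center_um + semi_axes_um > (dim - 1L) * spacing_um))
    stop("ellipsoid does not fit inside the field of view with a 1-voxel margin",
         call. = FALSE)
  for (core in necrotic_cores) {
    if (is.null(core$center_um) || is.null(core$radius_um))
      stop("each necrotic core needs center_um and radius_um", call. = FALSE)
    u <- (as.numeric(core$center_um) - center_um) / semi_axes_um
    if (sqrt(sum(u^2)) + core$radius_um / min(semi_axes_um) > 1)
      stop("necrotic core extends outside the tumour", call. = FALSE)
  }
  structure(list(semi_axes_um = semi_axes_um, spacing_um = as.numeric(spacing_um),
                 dim = dim, center_um = center_um,
                 tumour_intensity = tumour_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 psf_sigma_um = psf_sigma_um, necrotic_cores = necrotic_cores,
                 supersampling = as.integer(supersampling), seed = seed),
            class = "phantom_spec")
}

# Per-voxel occupancy fraction of an ellipsoid on the voxel grid.
# Voxel (i,j,k) (1-based) spans [(i-1)*s, i*s]; its centre is (i-0.5)*s.
# Conservative banding in the normalised radius (1-Lipschitz in the scaled
# norm) classifies clearly-inside/outside voxels exactly; only voxels in the
# rim band are supersampled.
ellipsoid_occupancy <- function(dim, spacing_um, center_um, semi_axes_um, ss) {
  ax <- lapply(1:3, function(k)
    ((seq_len(dim[k]) - 0.5) * spacing_um[k] - center_um[k]) / semi_axes_um[k])
  rc2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rc <- sqrt(rc2)
  hd <- 0.5 * sqrt(sum((spacing_um / semi_axes_um)^2))
  occ <- array(0, dim)
  occ[rc <= 1 - hd] <- 1
  band <- which(rc > 1 - hd & rc < 1 + hd)
  if (length(band)) {
    idx <- arrayInd(band, dim)
    cen <- sweep(idx - 0.5, 2, spacing_um, "*")
    offs1 <- ((seq_len(ss) - 0.5) / ss - 0.5)
    counts <- numeric(length(band))
    for (o1 in offs1) for (o2 in offs1) for (o3 in offs1) {
      u1 <- (cen[, 1] + o1 * spacing_um[1] - center_um[1]) / semi_axes_um[1]
      u2 <- (cen[, 2] + o2 * spacing_um[2] - center_um[2]) / semi_axes_um[2]
      u3 <- (cen[, 3] + o3 * spacing_um[3] - center_um[3]) / semi_axes_um[3]
      counts <- counts + (u1 * u1 + u2 * u2 + u3 * u3 <= 1)
    }
    occ[band] <- counts / ss^3
  }
  occ
}

# Separable Gaussian blur with per-axis sigma in voxel units; truncated at
# 3 sigma, kernel renormalised, replicate padding at the edges.
gaussian_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-rad, rad))^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n <- db[1]
    padded <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                    m[rep(n, rad), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * padded[t:(t + n - 1L), , drop = FALSE]
    a <- aperm(array(out, db), order(perm))
  }
  a
}

#' Render a synthetic tumour phantom
#'
#' Computes each voxel's tumour occupancy fraction (supersampled at the
#' rim), maps occupancy linearly onto
#' `background + occupancy * (tumour - background)`, renders necrotic cores
#' at their own intensity inside the tumour, then applies optional Gaussian
#' blur and seeded noise. Negative intensities after Gaussian noise are
#' clamped to zero (magnitude images are nonnegative).
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (an [image_volume]), `truth` (a [seg_mask]:
#'   occupancy >= 0.5, unbiased for symmetric bodies), `occupancy` (numeric
#'   array), `analytic_volume_mm3` (`(4*pi/3) a b c`, the primary ground
#'   truth), `analytic_mass_g` (at density 1.0), and `spec`.
#' @examples
#' p <- render_phantom(phantom_spec(1500, c(160, 160, 160), seed = 1))
#' p$analytic_volume_mm3   # 14.137 mm^3
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  occ <- ellipsoid_occupancy(spec$dim, spec$spacing_um, spec$center_um,
                             spec$semi_axes_um, spec$supersampling)
  img <- spec$background_intensity +
    occ * (spec$tumour_intensity - spec$background_intensity)
  for (core in spec$necrotic_cores) {
    core_int <- if (is.null(core$intensity)) spec$background_intensity else core$intensity
    occ_c <- ellipsoid_occupancy(spec$dim, spec$spacing_um,
                                 as.numeric(core$center_um),
                                 rep(core$radius_um, 3L), spec$supersampling)
    img <- img + occ_c * (core_int - spec$tumour_intensity)
  }
  if (spec$psf_sigma_um > 0)
    img <- gaussian_blur3(img, spec$psf_sigma_um / spec$spacing_um)
  if (spec$noise_sigma > 0) {
    if (is.null(spec$seed))
      stop("a seed is required when noise_sigma > 0", call. = FALSE)
    img <- withr::with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        pmax(img + stats::rnorm(length(img), sd = spec$noise_sigma), 0)
      } else {
        sqrt((img + stats::rnorm(length(img), sd = spec$noise_sigma))^2 +
               stats::rnorm(length(img), sd = spec$noise_sigma)^2)
      }
    })
    img <- array(img, spec$dim)
  }
  truth <- seg_mask(occ >= 0.5, list(list(op = "ground_truth",
                                          source = "phantom occupancy >= 0.5")))
  v_mm3 <- 4 * pi / 3 * prod(spec$semi_axes_um) / 1e9
  list(image = image_volume(img, spec$spacing_um),
       truth = truth,
       occupancy = occ,
       analytic_volume_mm3 = v_mm3,
       analytic_mass_g = v_mm3 / 1000,
       spec = spec)
}

#' Default study-style mass cohort
#'
#' Seventeen tumour masses log-spaced over 0.01-2.28 g, the size range of
#' the subcutaneous xenograft cohort the phantom suite emulates.
#'
#' @return Numeric vector of masses in grams.
#' @export
default_phantom_masses <- function() {
  signif(exp(seq(log(0.01), log(2.28), length.out = 17)), 3)
}

#' Default acquisition geometries
#'
#' Voxel spacings `(slice, row, column)` in um for the four protocols the
#' suite emulates: isotropic 3D volumes at 160, 200 and 240 um, and a
#' thick-slice 2D stack (700 um slices over 150 x 200 um pixels).
#'
#' @return Named list of length-3 spacing vectors.
#' @export
default_phantom_geometries <- function() {
  list(`3D-160` = c(160, 160, 160),
       `3D-200` = c(200, 200, 200),
       `3D-240` = c(240, 240, 240),
       `2D`     = c(700, 150, 200))
}

#' Generate a suite of spherical phantoms emulating a tumour cohort
#'
#' Converts each mass to a sphere at density 1.0 g/cm^3 and pairs it with
#' every acquisition geometry. Rendering is deferred: each case carries a
#' [phantom_spec] to pass to [render_phantom], keeping memory use flat when
#' iterating over large suites.
#'
#' @param masses_g Tumour masses (g); default [default_phantom_masses()].
#' @param geometries Named list of spacing triples (um); default
#'   [default_phantom_geometries()].
#' @param noise_sigma,psf_sigma_um,supersampling Passed to [phantom_spec].
#' @param seed Integer base seed; case `i` uses `seed + i`.
#' @param dir Optional directory: writes each rendered image as NIfTI plus
#'   a JSON manifest (`manifest.json`) with per-case analytic masses and
#'   seeds.
#' @return List with `cases` (list of [phantom_spec]) and `manifest`
#'   (`data.frame`: case_id, mass_g, geometry, spacing, diameter_um,
#'   min ratio across axes, analytic_mass_g, seed, and file if written).
#' @export
phantom_suite <- function(masses_g = default_phantom_masses(),
                          geometries = default_phantom_geometries(),
                          noise_sigma = 0, psf_sigma_um = 0,
                          supersampling = 4L, seed = 1L, dir = NULL) {
  stopifnot(all(masses_g > 0))
  if (is.null(names(geometries)))
    names(geometries) <- vapply(geometries, function(s)
      paste(s, collapse = "x"), character(1))
  cases <- list()
  rows <- list()
  i <- 0L
  for (gname in names(geometries)) {
    sp <- geometries[[gname]]
    for (m in masses_g) {
      i <- i + 1L
      d_um <- mass_to_diameter_um(m)
      spec <- phantom_spec(rep(d_um / 2, 3L), sp,
                           noise_sigma = noise_sigma,
                           psf_sigma_um = psf_sigma_um,
                           supersampling = supersampling,
                           seed = seed + i)
      case_id <- sprintf("case%03d_%s_%0.4gg", i, gname, m)
      cases[[case_id]] <- spec
      rows[[i]] <- data.frame(case_id = case_id, mass_g = m, geometry = gname,
                              spacing = paste(sp, collapse = "x"),
                              diameter_um = d_um,
                              ratio_min = min(d_um / sp),
                              analytic_mass_g = 4 * pi / 3 * (d_um / 2)^3 / 1e12,
                              seed = seed + i,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(nrow(manifest))
    for (k in seq_along(cases)) {
      ph <- render_phantom(cases[[k]])
      f <- file.path(dir, paste0(names(cases)[k], ".nii.gz"))
      write_image_volume(ph$image, f)
      files[k] <- f
    }
    manifest$file <- files
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, manifest = manifest)
}
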
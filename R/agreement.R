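#' Gauge-block (caliper) mass estimate
#'
#' External measurement of three perpendicular tumour diameters, converted
#' to volume under an ellipsoidal shape assumption, `V = (pi/6) l w h`, and
#' to mass via an assumed density.
#'
#' @param l_cm,w_cm,h_cm Length, width and height in cm.
#' @param density_g_cm3 Assumed density, g/cm^3 (default 1.0).
#' @return A [mass_estimate] with method `"gauge_block"`. Invariant under
#'   permutation of the three diameters.
#' @examples
#' gauge_block_mass(1, 1, 1)$mass_g   # pi/6 = 0.5236 g
#' @export
gauge_block_mass <- function(l_cm, w_cm, h_cm, density_g_cm3 = 1.0) {
  dims <- c(l_cm, w_cm, h_cm)
  if (!is.numeric(dims) || length(dims) != 3L || any(!is.finite(dims)) ||
      any(dims <= 0))
    stop("invalid measurement: l, w, h must be positive (cm)", call. = FALSE)
  v_mm3 <- pi / 6 * prod(dims) * 1000      # cm^3 -> mm^3
  mass_estimate(v_mm3, density_g_cm3, method = "gauge_block")
}

#' Coefficient of variation of a repeated-measurement series
#'
#' `100 * sd / mean`, using the sample (n-1) standard deviation. The
#' convention matters for short series (about 5 % at n = 10) and is fixed
#' here as the sample SD.
#'
#' @param values Numeric vector of repeated estimates (e.g. masses in g),
#'   n >= 2, positive mean.
#' @return CV in per cent (scale-invariant, >= 0).
#' @examples
#' coefficient_of_variation(c(1, 1, 1, 3))   # 66.67 %
#' @export
coefficient_of_variation <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop("invalid series: need at least two non-missing values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("invalid series: mean must be positive", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Signed interobserver deviation
#'
#' Relative deviation, in per cent, of an observer's estimate from a
#' reference mean (typically the average of observer 1's repeated
#' measurements).
#'
#' @param reference_mean Reference mean (> 0), e.g. mean mass in g.
#' @param observer_value Observer estimate(s); vectorised.
#' @return Signed deviation(s) in per cent.
#' @export
interobserver_deviation <- function(reference_mean, observer_value) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      !is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be a single positive number", call. = FALSE)
  100 * (observer_value - reference_mean) / reference_mean
}

#' Ordinary least-squares line with Pearson r squared
#'
#' Fits `y = slope * x + intercept` by OLS (y on x) and reports the squared
#' Pearson correlation, the form used to compare image-derived masses with
#' reference masses (`m_est = a * m_ref + b`, R^2).
#'
#' @param x Predictor (reference masses, g); must not be constant.
#' @param y Response (estimated masses, g); same length as `x`, n >= 3.
#' @return Object of class `agreement_fit`: list with `slope`, `intercept`,
#'   `r_squared` (in `[0, 1]`) and `n`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least three paired observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate fit: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n = length(x)),
            class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf("<agreement_fit> y = %.3f x %+ .3f, R^2 = %.3f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Emulated intra-/interobserver phantom study
#'
#' Renders one noisy spherical phantom per acquisition geometry and
#' emulates observers as independent threshold choices: every segmentation
#' run perturbs the ideal midpoint threshold by a Gaussian fraction of the
#' tumour-background intensity difference, mimicking the subjectivity of
#' manual ROI placement. Observer 1 repeats the segmentation `n_repeats`
#' times (intraobserver series, summarised as a CV); the remaining
#' observers segment once each and are reported as signed deviations from
#' observer 1's mean.
#'
#' Thick-slice geometries concentrate more volume in rim voxels, so the
#' same threshold subjectivity moves more volume: 2D stacks are expected to
#' show larger interobserver deviations than isotropic 3D volumes on small
#' tumours.
#'
#' @param mass_g Phantom tumour mass (g).
#' @param geometries Named list of spacing triples (um).
#' @param n_observers Total number of observers (>= 2).
#' @param n_repeats Observer 1's repeat count.
#' @param noise_sigma Image noise SD as an intensity (tumour-background
#'   difference is 80 by default phantom contrast).
#' @param threshold_jitter SD of the threshold perturbation as a fraction
#'   of the tumour-background intensity difference.
#' @param seed Integer seed; all randomness derives from it.
#' @return List with `intra` (`data.frame`: geometry, mean_mass_g,
#'   cv_percent) and `inter` (`data.frame`: geometry, observer,
#'   mass_g, deviation_pct).
#' @export
simulate_observer_study <- function(mass_g = 0.02,
                                    geometries = list(`3D-160` = c(160, 160, 160),
                                                      `2D` = c(700, 150, 200)),
                                    n_observers = 3L, n_repeats = 10L,
                                    noise_sigma = 5, threshold_jitter = 0.1,
                                    seed = 1L) {
  stopifnot(n_observers >= 2L, n_repeats >= 2L)
  d_um <- mass_to_diameter_um(mass_g)
  intra <- list(); inter <- list()
  gi <- 0L
  for (gname in names(geometries)) {
    gi <- gi + 1L
    spec <- phantom_spec(rep(d_um / 2, 3L), geometries[[gname]],
                         noise_sigma = noise_sigma, seed = seed + gi)
    ph <- render_phantom(spec)
    contrast <- spec$tumour_intensity - spec$background_intensity
    midpoint <- (spec$tumour_intensity + spec$background_intensity) / 2
    conn <- if (spec$spacing_um[1] >= 2 * max(spec$spacing_um[2:3])) "2d4" else "3d6"
    one_run <- function(thr) {
      m <- apply_threshold(ph$image, threshold_plan(thr))
      m <- fill_interior(m, connectivity = conn)
      mask_to_mass(m, spec$spacing_um)$mass_g
    }
    jit <- withr::with_seed(seed + 1000L * gi,
                            stats::rnorm(n_repeats + n_observers - 1L,
                                         sd = threshold_jitter * contrast))
    obs1 <- vapply(jit[seq_len(n_repeats)],
                   function(e) one_run(midpoint + e), numeric(1))
    others <- vapply(jit[n_repeats + seq_len(n_observers - 1L)],
                     function(e) one_run(midpoint + e), numeric(1))
    intra[[gname]] <- data.frame(geometry = gname, mean_mass_g = mean(obs1),
                                 cv_percent = coefficient_of_variation(obs1),
                                 stringsAsFactors = FALSE)
    inter[[gname]] <- data.frame(geometry = gname,
                                 observer = paste0("obs", 1L + seq_along(others)),
                                 mass_g = others,
                                 deviation_pct = interobserver_deviation(mean(obs1),
                                                                         others),
                                 stringsAsFactors = FALSE)
  }
  list(intra = do.call(rbind, c(intra, list(make.row.names = FALSE))),
       inter = do.call(rbind, c(inter, list(make.row.names = FALSE))))
}
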
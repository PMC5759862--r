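#' @useDynLib ionplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Depth grid step for all depth-dose / LET curves, water-equivalent mm.
DEPTH_STEP <- 0.5

#' Default analytic beam-model coefficients
#'
#' Coefficients of the analytic pencil-beam model. The pristine proton
#' depth-dose follows the classical power-law range-energy parameterization
#' (exponent p = 1.77) with a range-straggling Gaussian convolution of width
#' \code{straggling_coef * (R/10)^0.935 * 10} mm. Helium uses the same
#' functional family with the straggling width scaled by
#' \code{he_straggling_factor} and an added exponential fragmentation tail
#' (\code{he_tail_fraction} of the peak, decay length \code{he_tail_decay_mm});
#' both ions carry a beamline momentum-spread floor \code{sigma_beam_mm} on
#' the range-spread width (smaller for helium, matching its sharper measured
#' distal falloffs).
#' Dose-averaged LET depth templates rise monotonically from
#' \code{let_entrance} to \code{let_peak} as \code{(z/R)^let_shape}; beyond
#' the peak, helium LET relaxes toward \code{let_tail_fraction * let_peak}
#' (the lighter, faster fragment field), while the proton curve carries no
#' dose there. Lateral spread grows as
#' \code{sigma(z) = sqrt(sigma0^2 + (mcs_coef * R * (z/R)^1.8)^2)} with the
#' helium multiple-scattering coefficient half the proton one.
#'
#' @param ion `"proton"` or `"helium"`.
#' @return Named list of model coefficients.
#' @export
beam_defaults <- function(ion = c("proton", "helium")) {
  ion <- match.arg(ion)
  base <- list(
    p_exponent = 1.77,
    shape_k = 0.0025,          # weight of the (R-z)^0.565 term, per mm
    straggling_coef = 0.012,   # cm-based Bortfeld-style coefficient
    ripple_sigma_mm = 2,
    mcs_coef = 0.05,           # lateral growth, fraction of range
    let_shape = 6
  )
  if (ion == "proton") {
    c(base, list(
      ion = "proton",
      straggling_factor = 1,
      sigma_beam_mm = 0.8,
      tail_fraction = 0,
      tail_decay_mm = 30,
      let_entrance = 2, let_peak = 9, let_tail_fraction = 1,
      mcs_factor = 1,
      lambda = 0.08
    ))
  } else {
    c(base, list(
      ion = "helium",
      straggling_factor = 0.5,
      sigma_beam_mm = 0.4,
      tail_fraction = 0.02,
      tail_decay_mm = 30,
      let_entrance = 4, let_peak = 40, let_tail_fraction = 0.1,
      mcs_factor = 0.5,
      lambda = 0.15
    ))
  }
}

.gauss_smooth <- function(y, step, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma / step))
  k <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(0, half))
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

.pristine_depth_dose <- function(depth, range_w, prm) {
  res <- pmax(range_w - depth, 0)
  res_c <- pmax(res, 0.05)           # clip integrable singularity at z = R
  d <- res_c^(1 / prm$p_exponent - 1) + prm$shape_k * res_c^(1 / prm$p_exponent)
  d[res <= 0] <- 0
  d
}

.range_straggling_mm <- function(range_w, prm) {
  # intrinsic range straggling plus the beamline momentum-spread floor
  mono <- prm$straggling_coef * (range_w / 10)^0.935 * 10 *
    prm$straggling_factor
  sqrt(mono^2 + prm$sigma_beam_mm^2)
}

#' Analytic Bragg depth-dose curve
#'
#' Builds a single-energy depth-dose curve for a proton or helium pencil beam
#' at the requested water-equivalent range (distal 80\% point, R80), on a
#' 0.5 mm depth grid, together with its dose-averaged LET profile. Helium
#' curves carry a small exponential fragmentation tail beyond the distal
#' falloff and may be broadened by a ripple filter (modelled as convolution
#' with a 2 mm Gaussian kernel); a ripple filter on a proton curve is
#' accepted with a warning since it is only meaningful for helium.
#'
#' @param ion `"proton"` or `"helium"`.
#' @param range_w Requested R80 in water-equivalent mm, within [10, 300].
#' @param ripple_filter Logical; broaden the peak with the ripple filter.
#' @param params Coefficients as produced by [beam_defaults()].
#' @param depth_max Maximum tabulated depth (mm); defaults to range + 60 mm.
#' @return Object of class `depth_dose_curve` with fields `ion`, `range_w`,
#'   `depth`, `dose` (Gy mm^2 per unit spot weight, peak-normalized),
#'   `let_d` (keV/um) and `ripple_filter`.
#' @export
bragg_curve <- function(ion = c("proton", "helium"), range_w,
                        ripple_filter = FALSE,
                        params = beam_defaults(ion),
                        depth_max = NULL) {
  ion <- match.arg(ion)
  if (!is.numeric(range_w) || length(range_w) != 1 || !is.finite(range_w) ||
      range_w < 10 || range_w > 300) {
    stop("range_w must be a single value within [10, 300] mm water-equivalent")
  }
  if (ripple_filter && ion == "proton") {
    warning("ripple filter is only meaningful for helium; applying anyway")
  }
  if (is.null(depth_max)) depth_max <- range_w + 60
  depth <- seq(0, depth_max, by = DEPTH_STEP)

  build <- function(r_nom) {
    core <- .pristine_depth_dose(depth, r_nom, params)
    core <- .gauss_smooth(core, DEPTH_STEP, .range_straggling_mm(r_nom, params))
    if (params$tail_fraction > 0) {
      gate <- 1 / (1 + exp(-(depth - r_nom) / 1))
      tail <- params$tail_fraction * max(core) *
        exp(-pmax(depth - r_nom, 0) / params$tail_decay_mm) * gate
      core <- core + tail
    }
    if (ripple_filter) core <- .gauss_smooth(core, DEPTH_STEP, params$ripple_sigma_mm)
    pmax(core, 0)
  }
  measure_r80 <- function(dose) .distal_crossing(depth, dose, 0.8 * max(dose))

  # fixed-point range correction: nudge the nominal range until the
  # measured distal 80% point matches the requested one
  r_nom <- range_w
  for (iter in 1:5) {
    dose <- build(r_nom)
    err <- range_w - measure_r80(dose)
    if (abs(err) < 0.2) break
    r_nom <- r_nom + err
  }
  dose <- dose / max(dose)

  structure(list(
    ion = ion, range_w = range_w, depth = depth, dose = dose,
    let_d = .let_template(depth, range_w, params),
    ripple_filter = ripple_filter, params = params
  ), class = "depth_dose_curve")
}

# distal (last) depth at which `dose` crosses `level`, linear interpolation
.distal_crossing <- function(depth, dose, level) {
  above <- which(dose >= level)
  if (!length(above)) return(NA_real_)
  i <- max(above)
  if (i == length(dose)) return(depth[i])
  d1 <- dose[i]; d2 <- dose[i + 1]
  depth[i] + (d1 - level) / (d1 - d2) * (depth[i + 1] - depth[i])
}

# proximal (first) crossing of `level`
.proximal_crossing <- function(depth, dose, level) {
  above <- which(dose >= level)
  if (!length(above)) return(NA_real_)
  i <- min(above)
  if (i == 1) return(depth[1])
  d0 <- dose[i - 1]; d1 <- dose[i]
  depth[i - 1] + (level - d0) / (d1 - d0) * (depth[i] - depth[i - 1])
}

#' Distal falloff width of a depth-dose curve
#'
#' Distance between the distal 80\% and 20\% dose levels, mm.
#' @param curve A [bragg_curve()] object.
#' @return Width in mm.
#' @export
distal_falloff <- function(curve) {
  .distal_crossing(curve$depth, curve$dose, 0.2 * max(curve$dose)) -
    .distal_crossing(curve$depth, curve$dose, 0.8 * max(curve$dose))
}

#' Peak width of a depth-dose curve at a dose fraction
#'
#' Distance between the proximal and distal crossings of
#' `frac * max(dose)`; `frac = 0.8` gives the 80\%-80\% peak width.
#' @param curve A [bragg_curve()] object.
#' @param frac Dose fraction in (0, 1).
#' @return Width in mm.
#' @export
peak_width <- function(curve, frac = 0.8) {
  lev <- frac * max(curve$dose)
  .distal_crossing(curve$depth, curve$dose, lev) -
    .proximal_crossing(curve$depth, curve$dose, lev)
}

.let_template <- function(depth, range_w, params) {
  s <- pmin(depth / range_w, 1)
  let <- params$let_entrance + (params$let_peak - params$let_entrance) *
    s^params$let_shape
  # Beyond the peak the residual dose is a fragment field whose
  # dose-averaged LET relaxes quickly to a low floor (irrelevant for
  # protons, whose tail dose vanishes).
  beyond <- depth > range_w
  if (any(beyond)) {
    floor_let <- params$let_tail_fraction * params$let_peak
    let[beyond] <- floor_let + (params$let_peak - floor_let) *
      exp(-(depth[beyond] - range_w) / 5)
  }
  let
}

#' Dose-averaged LET depth profile
#'
#' Monotone analytic template for the dose-averaged LET of a single pencil
#' beam: strictly increasing from the entrance value to the peak value at
#' the Bragg peak. At equal range and fractional depth the helium profile
#' lies strictly above the proton one.
#'
#' @inheritParams bragg_curve
#' @return Object with fields `depth` (mm) and `let_d` (keV/um).
#' @export
let_profile <- function(ion = c("proton", "helium"), range_w,
                        params = beam_defaults(ion), depth_max = NULL) {
  ion <- match.arg(ion)
  if (!is.numeric(range_w) || length(range_w) != 1 || !is.finite(range_w) ||
      range_w < 10 || range_w > 300) {
    stop("range_w must be a single value within [10, 300] mm water-equivalent")
  }
  if (is.null(depth_max)) depth_max <- range_w + 60
  depth <- seq(0, depth_max, by = DEPTH_STEP)
  list(ion = ion, range_w = range_w, depth = depth,
       let_d = .let_template(depth, range_w, params))
}

#' Lateral spread of a pencil beam
#'
#' Gaussian sigma of the lateral dose profile at a given water-equivalent
#' depth: initial spot size grown by multiple Coulomb scattering,
#' \code{sigma(z) = sqrt(sigma0^2 + (mcs_coef * mcs_factor * R * (z/R)^1.8)^2)}.
#' The helium scattering coefficient is half the proton one, so at equal
#' range and depth helium spots are narrower (equal only at z = 0).
#'
#' @inheritParams bragg_curve
#' @param depth Water-equivalent depth(s), mm; must be non-negative.
#' @param sigma0 Spot sigma at the surface, mm.
#' @return Sigma in mm (vectorized over `depth`).
#' @export
sigma_lateral <- function(ion = c("proton", "helium"), depth, range_w,
                          sigma0 = 3, params = beam_defaults(ion)) {
  ion <- match.arg(ion)
  if (any(depth < 0)) stop("depth must be non-negative")
  grow <- params$mcs_coef * params$mcs_factor * range_w *
    (pmax(depth, 0) / range_w)^1.8
  sqrt(sigma0^2 + grow^2)
}

#' Select energy layers covering a water-equivalent depth interval
#'
#' Arithmetic sequence of Bragg-peak ranges starting at `min_wed` with the
#' given spacing, extended until the interval `[min_wed, max_wed]` is
#' covered (last layer within one spacing of `max_wed` or beyond).
#'
#' @param min_wed,max_wed Water-equivalent interval bounds, mm (`min < max`).
#' @param spacing Bragg-peak spacing in water, mm (default 2; 1 mm is the
#'   tighter option for shallow helium targets).
#' @return Numeric vector of layer ranges (mm).
#' @export
select_energy_layers <- function(min_wed, max_wed, spacing = 2) {
  if (!(min_wed < max_wed)) stop("empty interval: min_wed must be < max_wed")
  if (spacing <= 0) stop("spacing must be positive")
  n <- ceiling((max_wed - min_wed) / spacing - 1e-9) + 1
  min_wed + spacing * (seq_len(n) - 1)
}
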
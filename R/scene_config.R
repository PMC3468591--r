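#' Scene configuration for a synthetic lake transect survey
#'
#' Describes the virtual lake and survey design used by [sample_survey()]:
#' a 1-D transect across a deep basin, a piecewise-linear bathymetry, a diel
#' light cycle, a vertically migrating zooplankton backscatter layer, and the
#' acoustic properties of the two latent target classes (small native prey,
#' sparse large predators). Defaults describe a 2000 m transect over a basin
#' reaching 100 m, surveyed hourly for two 24-hour periods.
#'
#' @param transect_length Transect length in metres.
#' @param max_depth Maximum water depth (m); depth bins cover 0 to this.
#' @param bathymetry_knots Two-column matrix of (distance m, bottom depth m)
#'   pairs; bottom depth is linearly interpolated between knots and must stay
#'   in (0, `max_depth`].
#' @param n_days Number of 24-hour survey periods (default 2).
#' @param hours_per_day Hours surveyed per day (24).
#' @param bin_depth,bin_dist Integration cell size: depth stratum (10 m) and
#'   horizontal section (100 m). Must divide `max_depth` / `transect_length`.
#' @param dawn_hour,dusk_hour Hours of first/last light (0-24).
#' @param thermocline_depth Depth (m) of the thermocline; the temperature
#'   profile inflects here and the night zooplankton layer sits at it.
#' @param zpl_night_center,zpl_day_center Depth (m) of the zooplankton layer
#'   centre at night / at full daylight.
#' @param zpl_night_sd,zpl_day_sd Vertical spread (m) of the layer at
#'   night / full daylight (daytime dispersal widens the layer).
#' @param zpl_nearshore_factor Multiplicative night-time nearshore
#'   enhancement of the layer amplitude (>= 1).
#' @param zpl_nearshore_scale E-folding distance (m) of the nearshore
#'   enhancement.
#' @param zpl_base_sv,zpl_amp Background volume backscattering strength (dB)
#'   and layer amplitude (dB) before clamping to `sv_band`.
#' @param sv_band Biologically meaningful Sv band (dB); the noise-free field
#'   is clamped to it before measurement noise is added.
#' @param prey_ts_mean,prey_ts_sd,prey_ts_range Target strength (dB) of prey
#'   targets: Normal mean/sd truncated to `prey_ts_range` (within
#'   \[-58, -41\] dB so a -40 dB rule separates classes by construction).
#' @param pred_ts_range Target strength range (dB) of predator targets,
#'   uniform within it; must lie within \[-40, -20\].
#' @param pred_fraction Baseline predator fraction in (0,1); scaled by the
#'   diel and nearshore biases in [predator_fraction()]. 0 disables predators.
#' @param pred_nearshore_scale E-folding distance (m) of the predators'
#'   nearshore bias.
#' @param temp_surface,temp_deep,temp_width Two-layer logistic temperature
#'   profile: surface/deep temperature (deg C) and transition width (m).
#' @param noise_sd Additive Gaussian measurement noise on Sv samples (dB).
#' @param dispersion Negative-binomial size parameter for per-bin prey count
#'   draws; `Inf` gives Poisson counts.
#' @param seed Integer seed; the whole survey is reproducible from it.
#'
#' @return An object of class `scene_config` (a validated list).
#' @examples
#' cfg <- scene_config(transect_length = 600, seed = 7)
#' bathymetry(300, cfg)
#' @export
scene_config <- function(transect_length = 2000,
                         max_depth = 100,
                         bathymetry_knots = cbind(
                           c(0, 400, 1000, 1600, 2000) / 2000 * transect_length,
                           c(15, 70, 100, 70, 15) / 100 * max_depth),
                         n_days = 2,
                         hours_per_day = 24,
                         bin_depth = 10,
                         bin_dist = 100,
                         dawn_hour = 7,
                         dusk_hour = 19,
                         thermocline_depth = 40,
                         zpl_night_center = 40,
                         zpl_day_center = 70,
                         zpl_night_sd = 6,
                         zpl_day_sd = 12,
                         zpl_nearshore_factor = 1.1,
                         zpl_nearshore_scale = 200,
                         zpl_base_sv = -87,
                         zpl_amp = 14,
                         sv_band = c(-90, -70),
                         prey_ts_mean = -50,
                         prey_ts_sd = 3,
                         prey_ts_range = c(-58, -41),
                         pred_ts_range = c(-38, -22),
                         pred_fraction = 0.15,
                         pred_nearshore_scale = 250,
                         temp_surface = 16,
                         temp_deep = 7,
                         temp_width = 4,
                         noise_sd = 1,
                         dispersion = 2,
                         seed = 1L) {
  cfg <- mget(names(formals()))
  cfg$bathymetry_knots <- as.matrix(cfg$bathymetry_knots)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  kn <- cfg$bathymetry_knots
  stopifnot(is.matrix(kn), ncol(kn) == 2, nrow(kn) >= 2)
  if (any(diff(kn[, 1]) <= 0)) stop("bathymetry_knots distances must increase")
  if (kn[1, 1] != 0 || kn[nrow(kn), 1] != cfg$transect_length)
    stop("bathymetry_knots must span [0, transect_length]")
  if (any(kn[, 2] <= 0) || any(kn[, 2] > cfg$max_depth))
    stop("bottom depth at every knot must lie in (0, max_depth]")
  if (cfg$max_depth %% cfg$bin_depth != 0)
    stop("bin_depth must divide max_depth")
  if (cfg$transect_length %% cfg$bin_dist != 0)
    stop("bin_dist must divide transect_length")
  if (!(cfg$dawn_hour >= 0 && cfg$dawn_hour < cfg$dusk_hour &&
        cfg$dusk_hour < 24))
    stop("need 0 <= dawn_hour < dusk_hour < 24")
  if (cfg$pred_fraction < 0 || cfg$pred_fraction > 1)
    stop("pred_fraction must lie in [0, 1]")
  if (cfg$prey_ts_range[1] < -58 || cfg$prey_ts_range[2] > -41)
    stop("prey_ts_range must lie within [-58, -41] dB")
  if (cfg$pred_ts_range[1] < -40 || cfg$pred_ts_range[2] > -20)
    stop("pred_ts_range must lie within [-40, -20] dB")
  if (cfg$hours_per_day != 24)
    stop("hours_per_day must be 24 (diel design)")
  invisible(cfg)
}

#' Bottom depth along the transect
#'
#' Piecewise-linear interpolation of the configured bathymetry knots; a 1-D
#' stand-in for a contour map of the basin.
#'
#' @param x Distance(s) along the transect (m), in `[0, transect_length]`.
#' @param config A [scene_config()].
#' @return Bottom depth(s) in metres, in (0, `max_depth`].
#' @export
bathymetry <- function(x, config) {
  if (any(x < 0 | x > config$transect_length))
    stop("x outside transect [0, ", config$transect_length, "]")
  kn <- config$bathymetry_knots
  stats::approx(kn[, 1], kn[, 2], xout = x, rule = 1)$y
}

#' Relative surface irradiance over the diel cycle
#'
#' Normalized photosynthetically-active-radiation forcing: zero at night and
#' a half-sinusoid between dawn and dusk peaking at midday.
#'
#' @param t Hour of day (fractional, any real; reduced modulo 24).
#' @param config A [scene_config()].
#' @return Relative PAR in \[0, 1\].
#' @export
par_cycle <- function(t, config) {
  h <- t %% 24
  up <- h >= config$dawn_hour & h <= config$dusk_hour
  out <- numeric(length(h))
  out[up] <- sin(pi * (h[up] - config$dawn_hour) /
                   (config$dusk_hour - config$dawn_hour))
  out
}

#' Two-layer temperature profile
#'
#' Logistic transition from `temp_surface` to `temp_deep` with inflection at
#' the thermocline. Deterministic in depth, so it carries no information
#' beyond Depth itself — model selection is expected to drop it.
#'
#' @param z Depth(s) in metres.
#' @param config A [scene_config()].
#' @return Temperature(s) in deg C.
#' @export
temperature_profile <- function(z, config) {
  config$temp_deep + (config$temp_surface - config$temp_deep) /
    (1 + exp((z - config$thermocline_depth) / config$temp_width))
}

#' Zooplankton volume backscattering field
#'
#' A Gaussian-in-depth scattering layer whose centre migrates between the
#' night-time aggregation depth (near the thermocline) and a deeper daytime
#' centre, widening with daylight (daytime dispersal), with a night-time
#' nearshore amplitude enhancement. The noise-free field is clamped to the
#' configured Sv band before optional Gaussian dB noise is added.
#'
#' @param t Hour (fractional; modulo 24 sets the light phase).
#' @param x Distance along transect (m).
#' @param z Depth (m).
#' @param config A [scene_config()].
#' @param noise_sd Measurement noise sd in dB; `0` (default) returns the
#'   deterministic field. Caller controls seeding.
#' @return Sv in dB (vectorized over equal-length t, x, z).
#' @export
zooplankton_field <- function(t, x, z, config, noise_sd = 0) {
  p <- par_cycle(t, config)
  centre <- config$zpl_night_center +
    p * (config$zpl_day_center - config$zpl_night_center)
  spread <- config$zpl_night_sd + p * (config$zpl_day_sd - config$zpl_night_sd)
  dshore <- pmin(x, config$transect_length - x)
  shore <- 1 + (config$zpl_nearshore_factor - 1) *
    exp(-dshore / config$zpl_nearshore_scale) * (1 - p)
  sv <- config$zpl_base_sv +
    config$zpl_amp * shore * exp(-(z - centre)^2 / (2 * spread^2))
  sv <- clamp(sv, config$sv_band[1], config$sv_band[2])
  if (noise_sd > 0) sv <- sv + rnorm(length(sv), 0, noise_sd)
  sv
}

#' Expected predator fraction of targets in a cell
#'
#' Large piscivorous salmonids are modelled as a baseline fraction of
#' acoustic targets, biased upward in daylight and near shore.
#'
#' @param t Hour (fractional).
#' @param x Distance along transect (m).
#' @param config A [scene_config()].
#' @return Expected proportion of targets that are predators, in \[0, 0.5\].
#' @export
predator_fraction <- function(t, x, config) {
  if (config$pred_fraction == 0) return(rep(0, length(t)))
  p <- par_cycle(t, config)
  dshore <- pmin(x, config$transect_length - x)
  pf <- config$pred_fraction * (0.3 + 1.4 * p) *
    (1 + 0.3 * exp(-dshore / config$pred_nearshore_scale))
  clamp(pf, 0, 0.5)
}

#' Ground-truth response functions on the link scale
#'
#' The generating model for expected prey counts per cell:
#' `lambda = exp(intercept + g_Zpl + g_Pred + g_Hour + g_Depth + g_Dist)`.
#' Default shapes: a quadratic dome in zooplankton availability with an
#' interior optimum (fish select rich but not maximal prey patches), a linear
#' link-scale decline in predation risk (exponential decay on the response
#' scale), a quadratic U over hour of day with minimum at midday, a
#' quadratic dome in
#' depth peaked at the thermocline, and a linear decline with distance from
#' shore.
#' Temperature carries no effect.
#'
#' @param intercept Link-scale intercept.
#' @param zpl_opt,zpl_halfwidth,zpl_gain Dome optimum (dB MVBS), half-width
#'   (dB) and height.
#' @param pred_slope Link-scale decline per unit predator fraction (>0).
#' @param hour_center,hour_gain U-shaped diel effect: quadratic with its
#'   minimum at `hour_center` (midday); a quadratic lies in the span of a
#'   k = 3 smooth, so the fitted hour effect can recover the truth exactly.
#' @param depth_center,depth_halfwidth,depth_gain Quadratic depth dome:
#'   peak location (m), half-width (m) and height. A quadratic dome lies in
#'   the span of a k = 3 smooth of depth, so the temperature profile (a
#'   deterministic transform of depth) carries no residual information and
#'   selection can drop it.
#' @param dist_slope Link-scale decline per metre of distance from shore.
#' @return Object of class `true_response`: evaluable curves `g_zpl`,
#'   `g_pred`, `g_hour`, `g_depth`, `g_dist`, the intercept, and a `shapes`
#'   tag vector (`dome`, `decay`, `U`, `peaked`, `monotone`).
#' @export
true_response <- function(intercept = -0.8,
                          zpl_opt = -79, zpl_halfwidth = 8, zpl_gain = 1.2,
                          pred_slope = 3,
                          hour_center = 13, hour_gain = 1.4,
                          depth_center = 40, depth_halfwidth = 60,
                          depth_gain = 1,
                          dist_slope = 0.0009) {
  force(zpl_opt); force(zpl_halfwidth); force(zpl_gain); force(pred_slope)
  force(hour_center); force(hour_gain); force(depth_center)
  force(depth_halfwidth); force(depth_gain); force(dist_slope)
  structure(list(
    intercept = intercept,
    g_zpl   = function(v) zpl_gain * (1 - ((v - zpl_opt) / zpl_halfwidth)^2),
    g_pred  = function(p) -pred_slope * p,
    g_hour  = function(h) hour_gain * (((h %% 24) - hour_center) / 12)^2,
    g_depth = function(z) depth_gain *
      (1 - ((z - depth_center) / depth_halfwidth)^2),
    g_dist  = function(d) -dist_slope * d,
    shapes = c(Zpl = "dome", Pred = "decay", Hour = "U",
               Depth = "peaked", Dist = "monotone")
  ), class = "true_response")
}

#' Expected prey count for predictor rows
#'
#' Evaluates the generating model `lambda = exp(a + sum g_i(V_i))` on a data
#' frame with columns `Zpl`, `Pred`, `Hour`, `Depth`, `Dist`.
#'
#' @param rows Data frame of predictor values.
#' @param truth A [true_response()].
#' @return Positive expected counts, one per row.
#' @export
fish_intensity <- function(rows, truth) {
  stopifnot(inherits(truth, "true_response"))
  eta <- truth$intercept +
    truth$g_zpl(rows$Zpl) + truth$g_pred(rows$Pred) +
    truth$g_hour(rows$Hour) + truth$g_depth(rows$Depth) +
    truth$g_dist(rows$Dist)
  exp(eta)
}
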
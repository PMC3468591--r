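#' Enumerate the integration cells of a survey design
#'
#' One row per (day, hour, distance bin, depth bin) cell, with bin centres,
#' the usable water span after blanking, a validity flag (the cell holds some
#' water between the near-transducer zone and the bottom blanking zone at its
#' centre), and the noise-free predictor values of the generating model.
#'
#' @param config A [scene_config()].
#' @return Data frame of cells with truth predictors attached.
#' @keywords internal
survey_grid <- function(config) {
  n_dist <- config$transect_length / config$bin_dist
  n_depth <- config$max_depth / config$bin_depth
  g <- expand.grid(
    i_depth = seq_len(n_depth) - 1L,
    i_dist = seq_len(n_dist) - 1L,
    hour = 0:23,
    day = seq_len(config$n_days)
  )
  g$x_c <- (g$i_dist + 0.5) * config$bin_dist
  g$z_top <- g$i_depth * config$bin_depth
  g$Depth <- g$z_top + config$bin_depth / 2
  bottom <- bathymetry(g$x_c, config)
  g$z_lo <- pmax(g$z_top, 1)
  g$z_hi <- pmin(g$z_top + config$bin_depth, bottom - 2.5)
  g$valid <- g$z_hi > g$z_lo
  g$Dist <- pmin(g$x_c, config$transect_length - g$x_c)
  g$Hour <- g$hour
  g$t_mid <- (g$day - 1) * 24 + g$hour + 0.5
  ## bin-scale food availability: noise-free MVBS over exactly the (x, z)
  ## positions the Sv sampler visits inside the cell, so the measured index
  ## is an unbiased (up to symmetric dB noise) estimate of this predictor
  bottom_ok <- function(zz, xx) zz <= bathymetry(xx, config) - 2.5
  lin <- 0
  cnt <- 0
  for (zo in seq(1.5, config$bin_depth, by = 2)) {
    zz <- g$z_top + zo
    for (xo in c(0.25, 0.75) * config$bin_dist) {
      xx <- g$i_dist * config$bin_dist + xo
      ok <- bottom_ok(zz, xx)
      lin <- lin + ok * 10^(zooplankton_field(g$t_mid, xx, zz, config) / 10)
      cnt <- cnt + ok
    }
  }
  g$Zpl <- ifelse(cnt > 0, 10 * log10(lin / pmax(cnt, 1)), NA_real_)
  g$Pred <- predator_fraction(g$t_mid, g$x_c, config)
  g
}

#' Simulate a multi-day hydroacoustic transect survey
#'
#' Draws, cell by cell, zero-inflated prey counts around the ground-truth
#' intensity surface, places single targets uniformly within their cells,
#' assigns target strengths by latent class (prey: truncated Normal within
#' the small-fish band; predators: uniform within the large-fish band), adds
#' a sparse predator class whose per-cell rate keeps the expected predator
#' fraction at [predator_fraction()], and lays volume-backscatter samples on
#' a regular grid through the water column each hour. Everything is
#' reproducible from `config$seed`, with independent sub-streams per
#' component.
#'
#' @param config A [scene_config()].
#' @param truth A [true_response()] (defaults to the package default truth).
#' @return A list of class `acoustic_survey`:
#' \describe{
#'   \item{targets}{`t_hour` (absolute hour in `[0, 24 n_days)`), `x_m`,
#'     `z_m`, `ts_db`, `latent_class` (`prey`/`predator`; synthetic only,
#'     never consumed by the processing pipeline).}
#'   \item{samples}{`t_hour`, `x_m`, `z_m`, `sv_db`.}
#'   \item{truth}{per-cell `day`, `hour`, `i_dist`, `i_depth`, `lambda`,
#'     `true_count`, `pred_count`, plus the noise-free predictors.}
#'   \item{config, truth_fns}{the inputs, for provenance.}
#' }
#' @examples
#' sv <- sample_survey(scene_config(transect_length = 600, n_days = 1,
#'                                  seed = 42))
#' nrow(sv$targets)
#' @export
sample_survey <- function(config, truth = true_response()) {
  validate_scene_config(config)
  g <- survey_grid(config)
  g <- g[g$valid, , drop = FALSE]
  lambda <- fish_intensity(g, truth)
  if (any(!is.finite(lambda))) {
    bad <- which(!is.finite(lambda))[1]
    stop(sprintf(
      "non-finite intensity in cell (day %d, hour %d, i_dist %d, i_depth %d)",
      g$day[bad], g$hour[bad], g$i_dist[bad], g$i_depth[bad]))
  }
  n_cell <- nrow(g)

  counts <- with_seed(component_seed(config$seed, 1L), {
    if (is.infinite(config$dispersion)) rpois(n_cell, lambda)
    else rnbinom(n_cell, size = config$dispersion, mu = lambda)
  })
  ## predator rate follows the diel/nearshore-biased risk field pf and scales
  ## with local target intensity, so the realized fraction of predator
  ## targets in a cell is an unbiased measure of pf
  pf <- g$Pred
  pred_rate <- ifelse(pf > 0, lambda * pf / (1 - pf), 0)
  pred_counts <- with_seed(component_seed(config$seed, 2L),
                           rpois(n_cell, pred_rate))

  targets <- with_seed(component_seed(config$seed, 3L), {
    place <- function(n_per_cell, ts_fun) {
      idx <- rep.int(seq_len(n_cell), n_per_cell)
      n <- length(idx)
      data.frame(
        t_hour = (g$day[idx] - 1) * 24 + g$hour[idx] + runif(n),
        x_m = g$i_dist[idx] * config$bin_dist + runif(n) * config$bin_dist,
        z_m = g$z_lo[idx] + runif(n) * (g$z_hi[idx] - g$z_lo[idx]),
        ts_db = ts_fun(n)
      )
    }
    prey_ts <- function(n) {
      # inverse-CDF truncated Normal keeps prey strictly inside the band
      lo <- stats::pnorm(config$prey_ts_range[1], config$prey_ts_mean,
                         config$prey_ts_sd)
      hi <- stats::pnorm(config$prey_ts_range[2], config$prey_ts_mean,
                         config$prey_ts_sd)
      stats::qnorm(lo + runif(n) * (hi - lo), config$prey_ts_mean,
                   config$prey_ts_sd)
    }
    pred_ts <- function(n) runif(n, config$pred_ts_range[1],
                                 config$pred_ts_range[2])
    prey <- place(counts, prey_ts)
    prey$latent_class <- rep("prey", nrow(prey))
    pred <- place(pred_counts, pred_ts)
    pred$latent_class <- rep("predator", nrow(pred))
    out <- rbind(prey, pred)
    out[order(out$t_hour, out$x_m, out$z_m), , drop = FALSE]
  })
  rownames(targets) <- NULL

  samples <- with_seed(component_seed(config$seed, 4L), {
    xg <- seq(config$bin_dist / 4, config$transect_length - config$bin_dist / 4,
              by = config$bin_dist / 2)
    zg <- seq(1.5, config$max_depth, by = 2)
    sg <- expand.grid(z_m = zg, x_m = xg)
    sg <- sg[sg$z_m <= bathymetry(sg$x_m, config) - 2.5, , drop = FALSE]
    hours <- 0:(24 * config$n_days - 1)
    n_rep <- nrow(sg)
    out <- data.frame(
      t_hour = rep(hours + 0.5, each = n_rep),
      x_m = rep(sg$x_m, times = length(hours)),
      z_m = rep(sg$z_m, times = length(hours))
    )
    out$sv_db <- zooplankton_field(out$t_hour, out$x_m, out$z_m, config,
                                   noise_sd = config$noise_sd)
    out
  })
  rownames(samples) <- NULL

  truth_table <- data.frame(
    day = g$day, hour = g$hour, i_dist = g$i_dist, i_depth = g$i_depth,
    lambda = lambda, true_count = counts, pred_count = pred_counts,
    Zpl = g$Zpl, Pred = g$Pred, Depth = g$Depth, Dist = g$Dist
  )

  structure(list(targets = targets, samples = samples, truth = truth_table,
                 config = config, truth_fns = truth),
            class = "acoustic_survey")
}

#' @export
print.acoustic_survey <- function(x, ...) {
  cat(sprintf(
    "acoustic_survey: %d days, %d targets (%d predator), %d Sv samples\n",
    x$config$n_days, nrow(x$targets),
    sum(x$targets$latent_class == "predator"), nrow(x$samples)))
  invisible(x)
}

#' Write a survey to delimited text files
#'
#' Writes `targets.csv` (`t_hour, x_m, z_m, ts_db, latent_class`),
#' `samples.csv` (`t_hour, x_m, z_m, sv_db`) and `truth.csv` to a directory.
#'
#' @param survey An `acoustic_survey`.
#' @param dir Output directory (created if needed).
#' @param latent Include the synthetic-only `latent_class` column (default
#'   TRUE).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir, latent = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tg <- survey$targets
  if (!latent) tg$latent_class <- NULL
  paths <- file.path(dir, c("targets.csv", "samples.csv", "truth.csv"))
  write.csv(tg, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(survey$samples, paths[2], row.names = FALSE, quote = FALSE)
  tr <- survey$truth
  names(tr)[names(tr) == "i_dist"] <- "dist_bin"
  names(tr)[names(tr) == "i_depth"] <- "depth_bin"
  write.csv(tr, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
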
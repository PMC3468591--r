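#' Remove records in the blanking zones
#'
#' Excludes the transducer near zone (first metre below the surface) and the
#' bottom blanking zone (last 2.5 m above the bottom) from target or sample
#' records.
#'
#' @param records Data frame with columns `x_m` and `z_m`.
#' @param bathy Function mapping distance (m) to bottom depth (m), e.g.
#'   `function(x) bathymetry(x, config)`.
#' @param near_zone Metres blanked below the transducer (default 1).
#' @param bottom_zone Metres blanked above the bottom (default 2.5).
#' @return The retained rows; the number removed is attached as attribute
#'   `n_removed` and logged.
#' @export
apply_blanking <- function(records, bathy, near_zone = 1, bottom_zone = 2.5) {
  keep <- records$z_m >= near_zone &
    records$z_m <= bathy(records$x_m) - bottom_zone
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  log_msg("blanking removed %d of %d records", sum(!keep), nrow(records))
  out
}

#' Keep single targets within the fish target-strength band
#'
#' Retains targets whose TS lies in the closed interval `ts_range`
#' (default -58 to -20 dB), excluding strong abiotic echoes and weak
#' planktonic ones. Idempotent.
#'
#' @param targets Data frame with column `ts_db`.
#' @param ts_range Closed acceptance interval in dB.
#' @return The retained rows, with attribute `n_removed`.
#' @export
filter_fish_targets <- function(targets, ts_range = c(-58, -20)) {
  keep <- targets$ts_db >= ts_range[1] & targets$ts_db <= ts_range[2]
  out <- targets[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Predation-risk index of a cell
#'
#' Proportion of accepted targets with TS strictly above the large-fish
#' threshold (default -40 dB, i.e. piscivorous salmonids over ~20 cm);
#' 0 for an empty cell (no evidence of predators).
#'
#' @param ts Vector of accepted target strengths (dB).
#' @param threshold Large-fish TS threshold (dB); ties fall to the prey side.
#' @return Proportion in \[0, 1\].
#' @export
predation_risk <- function(ts, threshold = -40) {
  if (length(ts) == 0) return(0)
  mean(ts > threshold)
}

#' Zooplankton availability index of a cell (MVBS)
#'
#' Keeps Sv samples within the closed zooplankton band (default -90 to
#' -70 dB), averages in the linear domain and re-expresses in dB:
#' `MVBS = 10 log10(mean(10^(sv/10)))`. Returns `NA` when no in-band sample
#' exists (the row is dropped later, never imputed).
#'
#' @param sv Vector of Sv samples (dB).
#' @param band Closed acceptance interval in dB.
#' @return MVBS in dB, or `NA_real_`.
#' @export
zooplankton_index <- function(sv, band = c(-90, -70)) {
  sv <- sv[sv >= band[1] & sv <= band[2]]
  if (length(sv) == 0) return(NA_real_)
  10 * log10(mean(10^(sv / 10)))
}

#' Integrate targets and samples into survey cells
#'
#' Assigns every accepted target and Sv sample to exactly one
#' (day, hour, distance bin, depth bin) cell via half-open `[a, b)` intervals
#' (a record exactly on the transect end falls in the last bin) and returns
#' one row per grid cell with fish count, large-target count and MVBS.
#'
#' @param targets Blanked, TS-filtered targets (`t_hour, x_m, z_m, ts_db`).
#' @param samples Blanked Sv samples (`t_hour, x_m, z_m, sv_db`).
#' @param config A [scene_config()] (or any list with `transect_length`,
#'   `max_depth`, `bin_dist`, `bin_depth`, `bathymetry_knots`, `n_days`).
#' @param pred_threshold Large-fish TS threshold (dB) for `n_large`.
#' @param sv_band Zooplankton Sv band for the MVBS.
#' @return Data frame of cells: `day, hour, i_dist, i_depth, n_fish,
#'   n_large, mvbs, valid` (valid = the cell top lies above the bottom
#'   blanking zone at the cell centre). `sum(n_fish)` equals the number of
#'   accepted targets.
#' @export
integrate_bins <- function(targets, samples, config,
                           pred_threshold = -40, sv_band = c(-90, -70)) {
  n_dist <- config$transect_length / config$bin_dist
  n_depth <- config$max_depth / config$bin_depth

  cell_of <- function(df, what) {
    i_dist <- pmin(floor(df$x_m / config$bin_dist), n_dist - 1)
    i_depth <- floor(df$z_m / config$bin_depth)
    bad <- df$x_m < 0 | df$x_m > config$transect_length |
      i_depth < 0 | i_depth >= n_depth | df$t_hour < 0
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf("%s record %d (t=%.2f, x=%.1f, z=%.1f) outside the grid",
                   what, j, df$t_hour[j], df$x_m[j], df$z_m[j]))
    }
    hour_abs <- floor(df$t_hour)
    data.frame(day = hour_abs %/% 24 + 1, hour = hour_abs %% 24,
               i_dist = i_dist, i_depth = i_depth)
  }

  g <- survey_grid(config)
  key <- function(d) paste(d$day, d$hour, d$i_dist, d$i_depth, sep = "|")
  gk <- key(g)

  bins <- data.frame(day = g$day, hour = g$hour, i_dist = g$i_dist,
                     i_depth = g$i_depth, valid = g$valid)
  bins$n_fish <- 0L
  bins$n_large <- 0L
  bins$mvbs <- NA_real_

  if (nrow(targets) > 0) {
    tc <- cell_of(targets, "target")
    tk <- key(tc)
    miss <- !(tk %in% gk)
    if (any(miss)) {
      j <- which(miss)[1]
      stop(sprintf("target record %d maps to no survey cell (day %d hour %d)",
                   j, tc$day[j], tc$hour[j]))
    }
    tab <- table(factor(tk, levels = gk))
    bins$n_fish <- as.integer(tab)
    large <- targets$ts_db > pred_threshold
    tab_l <- table(factor(tk[large], levels = gk))
    bins$n_large <- as.integer(tab_l)
  }

  if (nrow(samples) > 0) {
    sc <- cell_of(samples, "sample")
    sk <- key(sc)
    inb <- samples$sv_db >= sv_band[1] & samples$sv_db <= sv_band[2]
    if (any(inb)) {
      lin <- 10^(samples$sv_db[inb] / 10)
      sums <- rowsum(lin, sk[inb])
      cnts <- rowsum(rep(1, sum(inb)), sk[inb])
      mv <- 10 * log10(sums[, 1] / cnts[, 1])
      idx <- match(rownames(sums), gk)
      ok <- !is.na(idx)
      bins$mvbs[idx[ok]] <- mv[ok]
    }
  }
  bins
}

#' Build the predictor table from integrated cells
#'
#' One row per valid cell: response `F` (fish count), `presence`, predation
#' risk `Pred`, zooplankton availability `Zpl` (MVBS, dB), cell mid-`Depth`
#' (m), `Dist`ance to the nearer shore (m), `Hour` of day, `Temp`erature at
#' mid-depth (deg C) and `day`. Rows without any in-band Sv sample are
#' dropped (count logged), never imputed.
#'
#' Predation risk is the proportion of large (> -40 dB) targets among all
#' accepted targets. Large salmonids are mobile water-column hunters, so by
#' default the proportion is pooled over the depth cells of each
#' day x hour x distance column (`pred_scale = "column"`); were it computed
#' per cell, any cell holding a predator target would by construction also
#' register presence, and a presence/absence model could never express
#' declining occupancy with risk. The pooled proportion is shrunk toward the
#' hour's transect-wide proportion with `pred_shrink` pseudo-targets
#' (empirical-Bayes style), because a column with one or two targets says
#' almost nothing about local risk and its raw proportion is dominated by
#' which class happened to be detected. `pred_scale = "cell"` restores the
#' strictly per-cell raw index with the empty-cell convention Pred = 0.
#'
#' @param bins Output of [integrate_bins()].
#' @param config A [scene_config()] (bin geometry and temperature profile).
#' @param pred_scale Scale of the predation-risk index: `"column"` (default)
#'   or `"cell"` (raw per-cell proportion, 0 for an empty cell).
#' @param pred_shrink Pseudo-target weight of the shrinkage toward the
#'   hourly pooled proportion (column scale only; 0 disables shrinkage,
#'   leaving empty columns at the hourly proportion).
#' @return Data frame of predictor rows; dropped-row count in attribute
#'   `n_dropped` and the fish targets they carried in `n_dropped_fish`.
#' @export
build_predictor_table <- function(bins, config,
                                  pred_scale = c("column", "cell"),
                                  pred_shrink = 4) {
  pred_scale <- match.arg(pred_scale)
  b <- bins[bins$valid, , drop = FALSE]
  n_invalid_fish <- sum(bins$n_fish[!bins$valid])
  drop <- is.na(b$mvbs)
  n_dropped_fish <- sum(b$n_fish[drop]) + n_invalid_fish
  if (any(drop)) {
    log_msg("dropping %d cells without in-band Sv samples (%d fish targets)",
            sum(drop), n_dropped_fish)
  }
  b <- b[!drop, , drop = FALSE]
  x_c <- (b$i_dist + 0.5) * config$bin_dist
  pred_idx <- if (pred_scale == "cell") {
    ifelse(b$n_fish > 0, b$n_large / b$n_fish, 0)
  } else {
    ## pooled over depth per day x hour x distance column, then shrunk
    ## toward that hour's transect-wide proportion with `pred_shrink`
    ## pseudo-targets: a column with few (or no) targets carries little
    ## local evidence about risk — risk does not vanish where fish hide —
    ## while target-rich columns keep their own proportion
    col <- interaction(b$day, b$hour, b$i_dist, drop = TRUE)
    tot <- as.numeric(tapply(b$n_fish, col, sum)[col])
    lrg <- as.numeric(tapply(b$n_large, col, sum)[col])
    hr <- interaction(b$day, b$hour, drop = TRUE)
    tot_h <- as.numeric(tapply(b$n_fish, hr, sum)[hr])
    lrg_h <- as.numeric(tapply(b$n_large, hr, sum)[hr])
    p_h <- ifelse(tot_h > 0, lrg_h / tot_h, 0)
    (lrg + pred_shrink * p_h) / (tot + pred_shrink)
  }
  out <- data.frame(
    F = b$n_fish,
    presence = as.integer(b$n_fish > 0),
    Zpl = b$mvbs,
    Pred = pred_idx,
    Depth = (b$i_depth + 0.5) * config$bin_depth,
    Dist = pmin(x_c, config$transect_length - x_c),
    Hour = b$hour,
    Temp = temperature_profile((b$i_depth + 0.5) * config$bin_depth, config),
    day = b$day,
    i_dist = b$i_dist,
    i_depth = b$i_depth
  )
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "n_dropped_fish") <- n_dropped_fish
  out
}

#' Run the full echo-processing pipeline on a survey
#'
#' Blanking, TS filtering, echo integration and predictor-table construction
#' in one call.
#'
#' @param survey An `acoustic_survey` (or list with `targets`, `samples`).
#' @param config A [scene_config()]; defaults to `survey$config`.
#' @param ... Passed to [build_predictor_table()] (`pred_scale`,
#'   `pred_shrink`).
#' @return Predictor table as from [build_predictor_table()].
#' @examples
#' sv <- sample_survey(scene_config(transect_length = 600, n_days = 1,
#'                                  seed = 3))
#' head(process_survey(sv))
#' @export
process_survey <- function(survey, config = survey$config, ...) {
  bathy <- function(x) bathymetry(x, config)
  tg <- apply_blanking(survey$targets, bathy)
  tg <- filter_fish_targets(tg)
  sm <- apply_blanking(survey$samples, bathy)
  bins <- integrate_bins(tg, sm, config)
  build_predictor_table(bins, config, ...)
}
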
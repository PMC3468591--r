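#' Moran's I with permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the weight total. The permutation p-value is two-sided
#' around the null expectation `-1/(n-1)`, with the conventional +1
#' correction in numerator and denominator.
#'
#' @param values Numeric vector (n >= 2, non-constant).
#' @param weights n x n non-negative weight matrix, zero diagonal, not all
#'   zero.
#' @param n_perm Number of random relabelings (default 999).
#' @param seed Optional seed for the permutations.
#' @return List: `I`, `expected` (`-1/(n-1)`), `perm_p`, `n_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 2, is.matrix(weights), all(dim(weights) == n))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  s0 <- sum(weights)
  if (s0 <= 0) stop("weights must not be all zero")
  if (var(values) == 0) stop("Moran's I undefined for constant values")
  z <- values - mean(values)
  denom <- sum(z^2)
  stat <- function(zz) (n / s0) * as.numeric(t(zz) %*% weights %*% zz) / denom
  obs <- stat(z)
  expected <- -1 / (n - 1)
  perm_p <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(b) stat(z[sample.int(n)]),
                                   numeric(1)))
    perm_p <- (1 + sum(abs(perm - expected) >= abs(obs - expected) - 1e-12)) /
      (n_perm + 1)
  }
  list(I = obs, expected = expected, perm_p = perm_p, n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' (upper-tail) permutation test by simultaneous row/column permutation of
#' the second matrix (+1 correction).
#'
#' @param dist_a,dist_b Symmetric zero-diagonal matrices (or `dist`
#'   objects) of equal size, n >= 4.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return List: `r`, `perm_p`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = NULL) {
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  n <- nrow(a)
  stopifnot(n >= 4, all(dim(b) == n))
  if (max(abs(a - t(a))) > 1e-10 || max(abs(b - t(b))) > 1e-10)
    stop("matrices must be symmetric")
  ut <- upper.tri(a)
  if (var(a[ut]) == 0 || var(b[ut]) == 0)
    stop("Mantel test undefined for a constant matrix")
  obs <- cor(a[ut], b[ut])
  perm_p <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      cor(a[ut], b[idx, idx][ut])
    }, numeric(1)))
    perm_p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  }
  list(r = obs, perm_p = perm_p, n_perm = n_perm)
}

#' Residual autocorrelation and normality diagnostics
#'
#' Moran's I on deviance residuals with inverse-Euclidean-distance weights
#' over (Dist, Depth) within each hour of each day, averaged across hours
#' (weighted by group size); the permutation null permutes residuals within
#' hours. A Mantel test relates the residual-difference matrix `|e_i - e_j|`
#' to Euclidean distance over standardized (Dist, Depth, Hour); for tables
#' larger than `mantel_max_n` rows a seeded subsample is used (distance
#' matrices are quadratic in n). Residual skewness and excess kurtosis serve
#' as the normality check.
#'
#' @param model An `echogam_fit`.
#' @param table The predictor table the model was fitted on (row-aligned).
#' @param n_perm Permutations for both tests (default 999).
#' @param seed Seed for permutations and the Mantel subsample.
#' @param mantel_max_n Subsample cap for the Mantel test (default 400).
#' @return List: `morans_i`, `expected`, `morans_p`, `mantel_r`, `mantel_p`,
#'   `skewness`, `kurtosis`, `n_perm`, `seed`.
#' @export
residual_autocorrelation <- function(model, table, n_perm = 999, seed = 1,
                                     mantel_max_n = 400) {
  res <- as.numeric(residuals(model$fit, type = "deviance"))
  d <- model$data
  stopifnot(length(res) == nrow(d))
  grp <- interaction(d$day, d$Hour, drop = TRUE)
  groups <- split(seq_len(nrow(d)), grp)
  groups <- Filter(function(ix) length(ix) >= 3 && var(res[ix]) > 0, groups)

  winfo <- lapply(groups, function(ix) {
    dm <- as.matrix(dist(cbind(d$Dist[ix], d$Depth[ix])))
    w <- ifelse(dm > 0, 1 / dm, 0)
    diag(w) <- 0
    list(ix = ix, w = w, s0 = sum(w))
  })
  group_i <- function(e) {
    vapply(winfo, function(g) {
      z <- e[g$ix] - mean(e[g$ix])
      (length(g$ix) / g$s0) * as.numeric(t(z) %*% g$w %*% z) / sum(z^2)
    }, numeric(1))
  }
  sizes <- vapply(winfo, function(g) length(g$ix), numeric(1))
  avg_i <- function(e) sum(group_i(e) * sizes) / sum(sizes)
  obs_i <- avg_i(res)
  expected <- sum(-1 / (sizes - 1) * sizes) / sum(sizes)
  perm_i <- with_seed(component_seed(seed, 1L),
    vapply(seq_len(n_perm), function(b) {
      e <- res
      for (g in winfo) e[g$ix] <- e[g$ix][sample.int(length(g$ix))]
      avg_i(e)
    }, numeric(1)))
  morans_p <- (1 + sum(abs(perm_i - expected) >= abs(obs_i - expected) - 1e-12)) /
    (n_perm + 1)

  idx <- seq_len(nrow(d))
  if (length(idx) > mantel_max_n) {
    idx <- with_seed(component_seed(seed, 2L),
                     sort(sample(idx, mantel_max_n)))
  }
  st <- scale(cbind(d$Dist[idx], d$Depth[idx],
                    (d$day[idx] - 1) * 24 + d$Hour[idx]))
  mt <- mantel_test(dist(cbind(res[idx])), dist(st), n_perm = n_perm,
                    seed = component_seed(seed, 3L))

  list(morans_i = obs_i, expected = expected, morans_p = morans_p,
       mantel_r = mt$r, mantel_p = mt$perm_p,
       skewness = skewness(res), kurtosis = kurtosis(res),
       n_perm = n_perm, seed = seed)
}

#' Observed-versus-predicted validation metrics
#'
#' `r` is the Pearson correlation; `a` and `b` the intercept and slope of the
#' least-squares regression `obs = a + b pred` (ideal a = 0, b = 1);
#' `r2 = 100 r^2`; `RMSE = sqrt(mean((pred - obs)^2))`; and the average error
#' `AVE = mean(pred - obs)`, so a negative AVE means mean underprediction.
#'
#' @param obs,pred Equal-length numeric vectors (n > 2).
#' @return One-row data frame: `r, a, b, r2, rmse, ave, n`.
#' @export
validation_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 2)
  n <- length(obs)
  if (var(pred) > 0) {
    fit <- lm(obs ~ pred)
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    r <- cor(obs, pred)
  } else {
    a <- mean(obs); b <- NA_real_; r <- NA_real_
  }
  data.frame(r = r, a = a, b = b, r2 = 100 * r^2,
             rmse = sqrt(mean((pred - obs)^2)), ave = mean(pred - obs), n = n)
}

## Observed and model-scale predicted values for a family on given rows.
family_obs_pred <- function(model, rows) {
  fd <- family_data(rows, model$family)
  obs <- fd$data[[model$response]]
  pred <- predict_gam(model, fd$data)$fit
  list(obs = obs, pred = pred, n = nrow(fd$data))
}

#' Fit on day 1, validate on day 2
#'
#' For each requested family: forward-select (or fit a fixed predictor set)
#' on the day-1 rows, then predict the day-2 rows from the fitted functional
#' relationships. Returns Table-2-style metric blocks for both phases
#' (fitting adds percent deviance explained).
#'
#' @param table Predictor table with a `day` column containing 1 and 2.
#' @param families Families to run (default all four).
#' @param candidates Candidates for forward selection.
#' @param predictors Optional fixed predictor set; skips selection.
#' @param k,alpha Passed to [forward_select()] / [fit_gam()].
#' @return List of class `echogam_validation`: `models`, `traces`,
#'   `fitting` and `validation` (data frames, one row per family).
#' @export
split_fit_validate <- function(table, families = FAMILIES,
                               candidates = c("Zpl", "Pred", "Depth", "Dist",
                                              "Hour", "Temp"),
                               predictors = NULL, k = 3, alpha = 0.05) {
  if (!all(c(1, 2) %in% table$day))
    stop("table must contain day 1 and day 2 rows")
  day1 <- table[table$day == 1, , drop = FALSE]
  day2 <- table[table$day == 2, , drop = FALSE]
  models <- list(); traces <- list(); fit_rows <- list(); val_rows <- list()
  for (fam in families) {
    if (is.null(predictors)) {
      sel <- forward_select(day1, fam, candidates, k = k, alpha = alpha)
      m <- sel$model
      traces[[fam]] <- sel$trace
    } else {
      m <- fit_gam(day1, fam, predictors, k = k)
      traces[[fam]] <- NULL
    }
    models[[fam]] <- m
    op_fit <- family_obs_pred(m, day1)
    fr <- validation_metrics(op_fit$obs, op_fit$pred)
    fr$dev <- deviance_explained(m)
    fr <- cbind(family = fam, phase = "fitting", fr)
    op_val <- family_obs_pred(m, day2)
    vr <- cbind(family = fam, phase = "validation",
                validation_metrics(op_val$obs, op_val$pred))
    fit_rows[[fam]] <- fr
    val_rows[[fam]] <- vr
  }
  structure(list(models = models, traces = traces,
                 fitting = do.call(rbind, c(fit_rows,
                                            list(make.row.names = FALSE))),
                 validation = do.call(rbind, c(val_rows,
                                               list(make.row.names = FALSE)))),
            class = "echogam_validation")
}

#' @export
print.echogam_validation <- function(x, ...) {
  cat("Fitting (day 1):\n"); print(x$fitting, digits = 3)
  cat("Validation (day 2):\n"); print(x$validation, digits = 3)
  invisible(x)
}

#' Hourly diel trade-off summary
#'
#' Per-hour means of zooplankton availability, predation risk and fish
#' count, plus standardized anomalies of each hourly series
#' (`(hourly mean - mean of hourly means) / sd of hourly means`; all zero
#' for a constant series).
#'
#' @param table Predictor table with `Hour`, `Zpl`, `Pred`, `F`.
#' @return Data frame: `hour, mean_F, mean_Zpl, mean_Pred, f_anom, zpl_anom,
#'   pred_anom`.
#' @export
diel_tradeoff <- function(table) {
  hours <- sort(unique(table$Hour))
  agg <- function(v) vapply(hours,
                            function(h) mean(v[table$Hour == h], na.rm = TRUE),
                            numeric(1))
  anom <- function(m) {
    s <- sd(m)
    if (!is.finite(s) || s == 0) rep(0, length(m)) else (m - mean(m)) / s
  }
  mf <- agg(table$F); mz <- agg(table$Zpl); mp <- agg(table$Pred)
  data.frame(hour = hours, mean_F = mf, mean_Zpl = mz, mean_Pred = mp,
             f_anom = anom(mf), zpl_anom = anom(mz), pred_anom = anom(mp))
}

## Best piecewise-constant segmentation of x into <= 3 segments defined by
## two ordered cut points, by exhaustive SSE minimization on prefix sums.
best_two_changepoints <- function(x) {
  n <- length(x)
  S <- c(0, cumsum(x)); Q <- c(0, cumsum(x^2))
  sse <- function(i, j) Q[j + 1] - Q[i] - (S[j + 1] - S[i])^2 / (j - i + 1)
  best <- list(sse = Inf, b1 = NA, b2 = NA)
  for (b1 in 2:(n - 1)) for (b2 in (b1 + 1):n) {
    v <- sse(1, b1 - 1) + sse(b1, b2 - 1) + sse(b2, n)
    if (v < best$sse - 1e-12) best <- list(sse = v, b1 = b1, b2 = b2)
  }
  best$means <- c(mean(x[1:(best$b1 - 1)]),
                  mean(x[best$b1:(best$b2 - 1)]),
                  mean(x[best$b2:n]))
  best$reduction <- sse(1, n) - best$sse
  best
}

#' Detect diel thresholds in an hourly series
#'
#' Two-changepoint piecewise-constant fit by exhaustive SSE minimization
#' over ordered hour pairs. A changepoint whose adjacent segment means are
#' equal is degenerate and dropped (a pure step series yields a single
#' breakpoint). Significance of the total SSE reduction is assessed by
#' permuting the hour labels.
#'
#' @param series Numeric series of hourly values (length >= 6; hour labels
#'   assumed `0:(length-1)`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return List: `breakpoints` (hours at which a new regime starts; may be
#'   empty for a constant series), `means` (segment means), `p`,
#'   `sse_reduction`.
#' @export
detect_thresholds <- function(series, n_perm = 999, seed = NULL) {
  n <- length(series)
  stopifnot(n >= 6)
  if (var(series) == 0) {
    return(list(breakpoints = integer(0), means = mean(series[1]),
                p = NA_real_, sse_reduction = 0))
  }
  best <- best_two_changepoints(series)
  eps <- 1e-8 * max(1, diff(range(series)))
  bps <- integer(0)
  if (abs(best$means[1] - best$means[2]) > eps) bps <- c(bps, best$b1 - 1L)
  if (abs(best$means[2] - best$means[3]) > eps) bps <- c(bps, best$b2 - 1L)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    best_two_changepoints(series[sample.int(n)])$reduction, numeric(1)))
  p <- (1 + sum(perm >= best$reduction - 1e-12)) / (n_perm + 1)
  list(breakpoints = as.integer(bps), means = best$means, p = p,
       sse_reduction = best$reduction)
}
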
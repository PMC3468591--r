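test_that("intercept-only fits return the null model", {
  set.seed(1)
  d <- data.frame(F = rpois(100, 3) + 1L)
  d$presence <- 1L
  m <- fit_gam(d, "gaussian_presence", character(0))
  expect_equal(m$intercept, mean(log(d$F)))
  expect_equal(deviance_explained(m), 0)
})

test_that("deviance_explained matches hand computations", {
  # response {0,0,3,3}, model reproducing the group means exactly:
  # null deviance sum((y - 1.5)^2) = 9, residual 0
  expect_equal(deviance_explained(list(null_deviance = 9,
                                       residual_deviance = 0)), 100)
  expect_equal(deviance_explained(list(null_deviance = 9,
                                       residual_deviance = 9)), 0)
  expect_true(is.na(deviance_explained(list(null_deviance = 0,
                                            residual_deviance = 0))))
})

test_that("a Poisson log-linear signal is recovered on the link scale", {
  set.seed(42)
  n <- 2000
  V <- runif(n, -2, 2)
  d <- data.frame(F = rpois(n, exp(1 + 0.5 * V)), V = V)
  d$presence <- as.integer(d$F > 0)
  m <- fit_gam(d, "quasipoisson", "V")
  pe <- partial_effect(m, "V", sort(V))
  expect_gt(cor(pe$effect, 0.5 * sort(V)), 0.99)
})

test_that("a k=3 smooth reproduces an interior dome maximum", {
  set.seed(7)
  n <- 1500
  V <- runif(n, -85, -72)
  dome <- 1.2 * (1 - ((V + 79) / 8)^2)
  d <- data.frame(F = rpois(n, exp(0.5 + dome)), V = V)
  d$presence <- as.integer(d$F > 0)
  m <- fit_gam(d, "quasipoisson", "V")
  pe <- partial_effect(m, "V")
  expect_equal(classify_shape(pe$value, pe$effect), "dome")
  peak <- pe$value[which.max(pe$effect)]
  expect_lt(abs(peak - (-79)), 2)
})

test_that("classify_shape tags analytic curves correctly", {
  x <- seq(0, 1, length.out = 60)
  expect_equal(classify_shape(x, 2 * x), "increasing")
  expect_equal(classify_shape(x, -x), "decreasing")
  expect_equal(classify_shape(x, -(x - 0.5)^2), "dome")
  expect_equal(classify_shape(x, (x - 0.4)^2), "U")
  expect_equal(classify_shape(x, rep(1, 60)), "flat")
  # sampling density must not change the verdict
  xd <- c(seq(0, 0.9, length.out = 200), seq(0.9, 1, length.out = 500))
  expect_equal(classify_shape(xd, -(xd - 0.5)^2), "dome")
})

test_that("shape_conforms operationalizes the response tags", {
  x <- seq(0, 1, length.out = 80)
  expect_true(shape_conforms(x, -(x - 0.5)^2, "dome"))
  expect_false(shape_conforms(x, x, "dome"))
  expect_true(shape_conforms(x, (x - 0.5)^2, "U"))
  expect_true(shape_conforms(x, -2 * x, "decay"))
  # quadratic-basis terminal bend still counts as decay overall
  bent <- -2 * x + 0.35 * pmax(x - 0.8, 0)
  expect_true(shape_conforms(x, bent, "decay"))
  expect_false(shape_conforms(x, (x - 0.4)^2, "decay"))
  expect_true(shape_conforms(x, -(x - 0.45)^2, "peak",
                             peak_at = 0.45, peak_tol = 0.1))
  expect_false(shape_conforms(x, -(x - 0.45)^2, "peak",
                              peak_at = 0.1, peak_tol = 0.1))
})

test_that("forward selection picks an informative candidate first", {
  set.seed(3)
  n <- 800
  d <- data.frame(Zpl = runif(n), Pred = runif(n), Depth = runif(n))
  d$F <- rpois(n, exp(0.5 + 1.5 * d$Depth))
  d$presence <- as.integer(d$F > 0)
  sel <- forward_select(d, "quasipoisson",
                        candidates = c("Zpl", "Pred", "Depth"))
  expect_equal(sel$final[1], "Depth")
  expect_true(all(diff(c(sel$trace$score_before[1],
                         sel$trace$score_after[sel$trace$accepted])) < 0))
})

test_that("pure-noise candidates leave the intercept-only model", {
  # best-of-six selection inflates the family-wise accept rate well above
  # the per-test alpha, so this holds at stated seeds, not universally
  for (seed in c(3, 4, 6)) {
    sel <- forward_select(noise_table(seed = seed), "quasipoisson")
    expect_equal(length(sel$final), 0)
  }
})

test_that("selection trace records scores and decisions coherently", {
  tab <- small_table(2)
  sel <- forward_select(tab, "binomial")
  tr <- sel$trace
  expect_true(all(c("step", "candidate", "score_before", "score_after",
                    "lrt_p", "accepted") %in% names(tr)))
  acc <- tr[tr$accepted, ]
  expect_equal(nrow(acc), length(sel$final))
  expect_true(all(acc$score_after < acc$score_before))
  expect_true(all(acc$lrt_p < 0.05))
})

test_that("predictions reproduce fitted values with ordered intervals", {
  tab <- small_table(4)
  m <- fit_gam(tab, "quasipoisson", c("Zpl", "Depth"))
  pr <- predict_gam(m, tab)
  expect_equal(pr$fit, unname(fitted(m$fit)), tolerance = 1e-10)
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
  expect_false(any(pr$extrapolated))
  expect_error(predict_gam(m, tab[, c("F", "Pred")]), "Zpl")
})

test_that("prediction SE grows with extrapolation distance", {
  set.seed(5)
  d <- data.frame(F = rpois(300, 5), V = runif(300))
  d$presence <- as.integer(d$F > 0)
  m <- fit_gam(d, "quasipoisson", "V")
  nd <- data.frame(V = c(1.2, 1.6, 2.5))
  pr <- predict_gam(m, nd)
  expect_true(all(pr$extrapolated))
  expect_true(all(diff(pr$se_link) > 0))
})

test_that("hurdle combination equals its closed form and is monotone in p", {
  tab <- small_table(6)
  bi <- fit_gam(tab, "binomial", c("Zpl", "Hour"))
  ga <- fit_gam(tab, "gaussian_presence", c("Zpl", "Hour"))
  h <- hurdle_combine(bi, ga, tab)
  p <- predict_gam(bi, tab)$fit
  m <- predict(ga$fit, newdata = tab, type = "link")
  expect_equal(h, p * exp(as.numeric(m) + ga$scale / 2), tolerance = 1e-12)
  expect_true(all(h >= 0))
  hs <- hurdle_combine(bi, ga, tab, correction = "smearing")
  expect_equal(cor(h, hs), 1, tolerance = 1e-6)
})

test_that("binomial fit satisfies the intercept score equation", {
  tab <- small_table(8)
  m <- fit_gam(tab, "binomial", c("Zpl", "Depth", "Hour"))
  expect_lt(abs(mean(fitted(m$fit)) - mean(tab$presence)), 1e-6)
})

test_that("partial effects are centered over the training rows", {
  tab <- small_table(8)
  m <- fit_gam(tab, "quasipoisson", c("Zpl", "Depth"))
  pe <- partial_effect(m, "Zpl", m$data$Zpl)
  expect_lt(abs(mean(pe$effect)), 1e-8)
  expect_error(partial_effect(m, "Hour"), "not in model")
})

test_that("degenerate inputs are rejected with clear messages", {
  tab <- small_table(1)
  tab$const <- 1
  expect_error(fit_gam(tab, "quasipoisson", "const"), "constant|unique")
  expect_error(fit_gam(tab, "quasipoisson", "nope"), "not in table")
})

test_that("quasi-Poisson and negative-binomial fitted means agree", {
  tab <- small_table(10)
  qp <- fit_gam(tab, "quasipoisson", c("Zpl", "Depth", "Hour"))
  nb <- fit_gam(tab, "negbinomial", c("Zpl", "Depth", "Hour"))
  expect_gt(cor(fitted(qp$fit), fitted(nb$fit)), 0.95)
  expect_gt(nb$theta, 0)
})

test_that("Gaussian DEV is invariant to response rescaling", {
  tab <- small_table(12)
  m1 <- fit_gam(tab, "gaussian_presence", c("Zpl", "Hour"))
  tab2 <- tab
  tab2$F <- tab$F^2  # log response doubles: ln F^2 = 2 ln F
  m2 <- fit_gam(tab2, "gaussian_presence", c("Zpl", "Hour"))
  expect_equal(deviance_explained(m1), deviance_explained(m2),
               tolerance = 1e-6)
})
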
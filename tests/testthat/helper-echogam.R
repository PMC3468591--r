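## Shared fixtures and independent oracles.

ACTIVE <- c("Zpl", "Pred", "Depth", "Dist", "Hour")
CANDIDATES <- c("Zpl", "Pred", "Depth", "Dist", "Hour", "Temp")

## 600 m, one-day world: ~800 cells, generated in ~1 s.
small_scene <- function(seed = 1, ...) {
  scene_config(transect_length = 600, n_days = 1, seed = seed, ...)
}

small_table <- function(seed = 1, truth = true_response(), ...) {
  sv <- sample_survey(small_scene(seed, ...), truth)
  suppressMessages(process_survey(sv))
}

default_table <- function(seed = 1, truth = true_response()) {
  sv <- sample_survey(scene_config(seed = seed), truth)
  suppressMessages(process_survey(sv))
}

truth_funs <- function(tr = true_response()) {
  list(Zpl = tr$g_zpl, Pred = tr$g_pred, Depth = tr$g_depth,
       Dist = tr$g_dist, Hour = tr$g_hour)
}

## naive O(n^2) double-sum Moran's I (independent oracle)
moran_naive <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

## direct upper-triangle correlation (independent oracle for Mantel r)
mantel_naive <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  av <- c(); bv <- c()
  for (i in 1:(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    av <- c(av, a[i, j]); bv <- c(bv, b[i, j])
  }
  cor(av, bv)
}

random_weights <- function(n) {
  w <- matrix(runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

## pure-noise candidate table for selection tests
noise_table <- function(n = 500, seed = 1) {
  set.seed(seed)
  d <- data.frame(F = rpois(n, 5), Zpl = runif(n), Pred = runif(n),
                  Depth = runif(n), Dist = runif(n), Hour = runif(n),
                  Temp = runif(n))
  d$presence <- as.integer(d$F > 0)
  d
}
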
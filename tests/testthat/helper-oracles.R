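# Shared fixtures and independent oracles used across the suite.

make_samples <- function(v_recumbent, v_active) {
  tibble::tibble(
    v_mps = c(v_recumbent, v_active),
    code = rep(c(0L, 1L), c(length(v_recumbent), length(v_active)))
  )
}

# Brute-force enumeration of every classification the nonnegative-cutoff
# rule `1 iff v > t` can produce: thresholds at 0 and at each observed
# velocity. Returns the maximum accuracy in percent.
brute_force_best_accuracy <- function(v, code) {
  cand <- c(0, sort(unique(v)))
  max(vapply(cand, function(t) 100 * mean(as.integer(v > t) == code), numeric(1)))
}

# Interior-only Laplacian variance recomputed with explicit loops; the
# slow second code path the fast implementation is checked against.
slow_laplacian_variance <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  resp <- c()
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      resp <- c(resp, px[i - 1, j] + px[i + 1, j] + px[i, j - 1] + px[i, j + 1] -
                  4 * px[i, j])
    }
  }
  mean((resp - mean(resp))^2)
}

# Mean of max(X, 0) for X ~ Normal(mu, sigma): the expected per-frame
# speed after the generator's truncation at zero.
truncated_speed_mean <- function(mu, sigma) {
  if (sigma == 0) return(max(mu, 0))
  mu * stats::pnorm(mu / sigma) + sigma * stats::dnorm(mu / sigma)
}

# Two-cluster velocity samples mimicking a recumbent/active mixture:
# recumbent |N(0, sd0)|, active N(mu1, sd1), drawn with a fixed seed.
make_mixture_samples <- function(n, prop_active = 0.9, sd0 = 2e-4,
                                 mu1 = 0.02, sd1 = 0.003, seed = 1) {
  withr::with_seed(seed, {
    n1 <- round(n * prop_active)
    n0 <- n - n1
    make_samples(abs(stats::rnorm(n0, 0, sd0)),
                 pmax(stats::rnorm(n1, mu1, sd1), 0))
  })
}

quiet <- function(expr) suppressMessages(expr)
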
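# independent oracles used by the tests; deliberately naive implementations
# that do not share code with the package internals

# all permutations of 1:n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Kendall S between two vectors by direct pair counting
kendall_S_oracle <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  Vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_lo <- mean(Vs <= V_obs + 1e-9)
  p_hi <- mean(Vs >= V_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# PCA contribution oracle via direct eigen-decomposition of the sample
# covariance of standardized genes
pca_contrib_oracle <- function(x, component = 1) {
  # x: genes x samples
  xs <- t(scale(t(x)))           # standardize each gene
  xc <- scale(t(xs), scale = FALSE)    # center samples-by-genes
  ev <- eigen(stats::cov(xc))
  scores <- xc %*% ev$vectors[, component]
  100 * scores^2 / sum(scores^2)
}

# product-limit estimator by hand over distinct event times
km_oracle <- function(time, event, t_eval) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ev_times[ev_times <= t_eval]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# small deterministic cohort-like matrix with planted correlated pairs
make_planted_pairs_matrix <- function(n_samples, n_pairs, n_noise, seed) {
  withr::with_seed(seed, {
    genes <- list()
    for (k in seq_len(n_pairs)) {
      f <- rnorm(n_samples)
      genes[[sprintf("A%02d", k)]] <- f + 0.35 * rnorm(n_samples)
      genes[[sprintf("B%02d", k)]] <- f + 0.35 * rnorm(n_samples)
    }
    for (k in seq_len(n_noise)) {
      genes[[sprintf("N%02d", k)]] <- rnorm(n_samples)
    }
    m <- do.call(rbind, genes)
    colnames(m) <- sprintf("S%03d", seq_len(n_samples))
    m
  })
}
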
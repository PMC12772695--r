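# Shared fixtures and independent oracles for the test suite.

# Reference parameterization used throughout: mu = log 2, k = mu * M,
# deterministic halving.
ref_params <- function(alpha = 0, M = 1, mu = log(2), k = mu * M,
                       beta = 0.5) {
  model_params(mu = mu, alpha = alpha, k = k, M = M,
               partition = partition_rule("deterministic", beta))
}

# Quadrature oracle for the flow: t(s0 -> s1) = int (1 + alpha*s)/(mu*s) ds.
# Independent of the closed form used by flow_time().
flow_time_quad <- function(s0, s1, params) {
  stats::integrate(function(s) (1 + params$alpha * s) / (params$mu * s),
                   s0, s1, rel.tol = 1e-11)$value
}

# Random valid parameter set (fixed RNG state assumed set by the caller).
random_params <- function(M = 1L) {
  mu <- runif(1, 0.2, 3)
  kind <- sample(c("deterministic", "beta"), 1)
  m <- runif(1, 0.3, 0.7)
  part <- if (kind == "deterministic") {
    partition_rule("deterministic", m)
  } else {
    v <- runif(1, 0.05, 0.8) * m * (1 - m)   # admissible variance
    partition_rule("beta", m, m^2 + v)
  }
  model_params(mu = mu, alpha = runif(1, 0, 8), k = runif(1, 0.2, 5),
               M = M, partition = part)
}

# Batch-means standard error for autocorrelated per-cycle records.
batch_se <- function(x, n_batches = 50L) {
  b <- tapply(x, cut(seq_along(x), n_batches, labels = FALSE), mean)
  stats::sd(b) / sqrt(n_batches)
}
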
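# Independent brute-force oracles, written against the model definition
# (explicit loops over configurations), deliberately sharing no code with
# the package internals they check.

# all 0/1 vectors of length S, as a list, in no particular required order
oracle_all_configs <- function(S) {
  g <- do.call(expand.grid, rep(list(c(0, 1)), S))
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}

# double-loop evaluation of the exponent at one configuration
oracle_potential <- function(y, x, alpha, beta) {
  tot <- 0
  for (i in seq_along(y)) {
    tot <- tot + sum(alpha[i, ] * x) * y[i]
  }
  for (i in seq_along(y)) {
    for (j in seq_along(y)) {
      if (i < j) tot <- tot + beta[i, j] * y[i] * y[j]
    }
  }
  tot
}

oracle_partition <- function(x, alpha, beta) {
  sum(vapply(oracle_all_configs(nrow(alpha)),
             function(y) exp(oracle_potential(y, x, alpha, beta)), numeric(1)))
}

# exact configuration distribution as a named probability vector keyed by
# the pasted configuration string
oracle_config_probs <- function(x, alpha, beta) {
  cfgs <- oracle_all_configs(nrow(alpha))
  w <- vapply(cfgs, function(y) exp(oracle_potential(y, x, alpha, beta)), numeric(1))
  stats::setNames(w / sum(w),
                  vapply(cfgs, paste, character(1), collapse = ""))
}

# random parameter draw for property tests
random_params <- function(S, K = 1, seed = 1, scale = 0.8) {
  set.seed(seed)
  alpha <- matrix(stats::rnorm(S * K, 0, scale), S, K)
  b <- matrix(0, S, S)
  b[upper.tri(b)] <- stats::rnorm(S * (S - 1) / 2, 0, scale)
  b <- b + t(b)
  mrf_params(alpha, b)
}

intercept_covars <- function(n) {
  covariate_matrix(matrix(1, n, 1), factor_names = "intercept")
}

# empirical configuration frequencies of a community matrix, keyed like
# oracle_config_probs
config_freqs <- function(data) {
  keys <- apply(unclass(data), 1, paste, collapse = "")
  tab <- table(keys)
  stats::setNames(as.numeric(tab) / nrow(data), names(tab))
}
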
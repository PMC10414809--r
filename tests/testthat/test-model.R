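# The probability model: potentials, partition function, likelihood.

test_that("log_potential matches hand evaluation and the double-loop oracle", {
  p <- mrf_params(alpha = matrix(c(0.2, -0.1), 2, 1),
                  beta = matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_equal(log_potential(c(0, 0), 1, p), 0)
  expect_equal(log_potential(c(1, 1), 1, p), 0.4)
  p1 <- mrf_params(matrix(0.5, 1, 1), matrix(0, 1, 1))
  expect_equal(log_potential(1, 1, p1), 0.5)
  # random cases against the independent oracle
  for (s in 1:5) {
    pr <- random_params(4, K = 2, seed = s)
    x <- c(1, 0.7)
    for (y in oracle_all_configs(4)[c(1, 6, 16)]) {
      expect_equal(log_potential(y, x, pr),
                   oracle_potential(y, x, pr$alpha, pr$beta))
    }
  }
  expect_error(log_potential(c(1, 1, 1), 1, p), "dimension")
})

test_that("log_partition equals brute-force enumeration up to S = 6", {
  p0 <- mrf_params(matrix(0, 2, 1), matrix(0, 2, 2))
  expect_equal(log_partition(1, p0), log(4))
  expect_equal(log_partition(1, mrf_params(matrix(0, 1, 1), matrix(0, 1, 1))),
               log(2))
  for (S in 2:6) {
    pr <- random_params(S, K = 2, seed = S + 10)
    x <- c(1, -0.4)
    expect_equal(exp(log_partition(x, pr)), oracle_partition(x, pr$alpha, pr$beta),
                 tolerance = 1e-10)
  }
})

test_that("enumeration refuses above the limit with a pseudolikelihood hint", {
  big <- mrf_params(matrix(0, 21, 1), matrix(0, 21, 21))
  expect_error(log_partition(1, big), "pseudolikelihood")
})

test_that("configuration probabilities normalize and match the oracle", {
  p0 <- mrf_params(matrix(0, 2, 1), matrix(0, 2, 2))
  expect_equal(configuration_probabilities(1, p0)$probability, rep(0.25, 4))
  for (s in 1:5) {
    pr <- random_params(3, seed = 100 + s)
    cp <- configuration_probabilities(1, pr)
    expect_equal(sum(cp$probability), 1, tolerance = 1e-12)
    keys <- apply(cp[, seq_len(3)], 1, paste, collapse = "")
    orc <- oracle_config_probs(1, pr$alpha, pr$beta)
    expect_equal(cp$probability, unname(orc[keys]), tolerance = 1e-12)
  }
  # strong positive association makes joint presence the modal configuration
  pb <- mrf_params(matrix(0, 2, 1), matrix(c(0, 2, 2, 0), 2, 2))
  cp <- configuration_probabilities(1, pb)
  expect_equal(which.max(cp$probability), which(cp[[1]] == 1 & cp[[2]] == 1))
})

test_that("increasing beta_ij strictly raises the joint-presence probability", {
  joint_p <- function(b12) {
    pr <- mrf_params(matrix(c(0.3, -0.2), 2, 1),
                     matrix(c(0, b12, b12, 0), 2, 2))
    cp <- configuration_probabilities(1, pr)
    cp$probability[cp[[1]] == 1 & cp[[2]] == 1]
  }
  v <- vapply(seq(-1, 1, by = 0.25), joint_p, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("log_likelihood is additive, permutation-symmetric and <= 0", {
  pr <- random_params(3, seed = 7)
  x <- intercept_covars(6)
  set.seed(7)
  Y <- matrix(rbinom(18, 1, 0.5), 6, 3)
  d <- community_matrix(Y)
  ll <- log_likelihood(d, x, pr)
  expect_lt(ll, 0)
  # additivity over site subsets
  d1 <- community_matrix(Y[1:2, , drop = FALSE], site_ids = c("a", "b"))
  d2 <- community_matrix(Y[3:6, , drop = FALSE], site_ids = c("c", "d", "e", "f"))
  expect_equal(ll, log_likelihood(d1, NULL, pr) + log_likelihood(d2, NULL, pr))
  # two identical sites double the single-site value
  ds <- community_matrix(Y[c(1, 1), , drop = FALSE], site_ids = c("a", "b"))
  d11 <- community_matrix(Y[1, , drop = FALSE], site_ids = "a")
  expect_equal(log_likelihood(ds, NULL, pr), 2 * log_likelihood(d11, NULL, pr))
  # species relabelling symmetry
  perm <- c(3, 1, 2)
  pr_p <- mrf_params(pr$alpha[perm, , drop = FALSE], pr$beta[perm, perm])
  d_p <- community_matrix(Y[, perm])
  expect_equal(log_likelihood(d_p, x, pr_p), ll)
  # uniform model on one site gives -S log 2
  p0 <- mrf_params(matrix(0, 3, 1), matrix(0, 3, 3))
  expect_equal(log_likelihood(d11, NULL, p0), -3 * log(2))
  # matches the enumerated probability product
  orc <- oracle_config_probs(1, pr$alpha, pr$beta)
  keys <- apply(Y, 1, paste, collapse = "")
  expect_equal(ll, sum(log(orc[keys])))
})

test_that("abundance matrices are rejected with a pointer to count models", {
  d <- community_matrix(matrix(c(0, 2, 1, 1), 2, 2))
  expect_error(log_likelihood(d, NULL, random_params(2)), "abundance|poisson")
})
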
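# Inference: exact maximum likelihood, pseudolikelihood, count models.

test_that("exact ML recovers the null on independent 50% data", {
  p0 <- mrf_params(matrix(0, 3, 1), matrix(0, 3, 3))
  d <- gibbs_sample(p0, intercept_covars(2000), seed = 11)
  f <- mrf_fit(d, NULL, method = "exact")
  expect_true(f$converged)
  expect_lt(max(abs(coef(f)$alpha)), 0.15)
  expect_lt(max(abs(coef(f)$beta)), 0.2)
})

test_that("exact ML recovers generating signs and satisfies moment matching", {
  truth <- random_params(3, seed = 1, scale = 0)
  truth$beta[1, 2] <- truth$beta[2, 1] <- 0.9
  truth$beta[1, 3] <- truth$beta[3, 1] <- -0.9
  truth$alpha[, 1] <- c(0.4, -0.2, 0.1)
  cv <- intercept_covars(2000)
  d <- gibbs_sample(truth, cv, seed = 21)
  f <- mrf_fit(d, cv, method = "exact", penalty = 0, tol = 1e-8)
  expect_true(f$converged)
  bh <- coef(f)$beta
  expect_equal(sign(bh[1, 2]), 1)
  expect_equal(sign(bh[1, 3]), -1)
  expect_lt(abs(bh[2, 3]), 0.35)
  # exponential-family stationarity: expected pairwise co-occurrence under
  # the fitted model equals the empirical co-occurrence frequency
  cp <- configuration_probabilities(1, f$params)
  Yc <- as.matrix(cp[, 1:3])
  emp <- crossprod(unclass(d)) / nrow(d)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sum(cp$probability * Yc[, i] * Yc[, j]), emp[i, j],
                 tolerance = 1e-6)
  }
  # marginal occurrence matching, too
  for (i in 1:3) {
    expect_equal(sum(cp$probability * Yc[, i]), mean(unclass(d)[, i]),
                 tolerance = 1e-6)
  }
  # fitted likelihood is at least the generating-parameter likelihood
  expect_gte(log_likelihood(d, cv, f$params), log_likelihood(d, cv, truth))
})

test_that("pseudolikelihood agrees with exact ML and is exactly symmetric", {
  truth <- random_params(3, seed = 2, scale = 0)
  truth$beta[1, 2] <- truth$beta[2, 1] <- 0.75
  truth$beta[2, 3] <- truth$beta[3, 2] <- -0.75
  truth$alpha[, 1] <- c(0.2, 0, -0.3)
  cv <- intercept_covars(2000)
  d <- gibbs_sample(truth, cv, seed = 31)
  fe <- mrf_fit(d, cv, method = "exact")
  fp <- mrf_fit(d, cv, method = "pseudolikelihood")
  expect_identical(fp$params$beta, t(fp$params$beta))
  ut <- upper.tri(truth$beta)
  expect_gt(cor(coef(fe)$beta[ut], coef(fp)$beta[ut]), 0.9)
  expect_gt(cor(as.vector(coef(fe)$alpha), as.vector(coef(fp)$alpha)), 0.9)
})

test_that("pseudolikelihood approaches exact ML as sites grow", {
  truth <- random_params(3, seed = 3, scale = 0)
  truth$beta[1, 2] <- truth$beta[2, 1] <- 0.75
  gap <- vapply(c(300, 3000), function(n) {
    cv <- intercept_covars(n)
    d <- gibbs_sample(truth, cv, seed = 41)
    fe <- mrf_fit(d, cv, method = "exact", penalty = 0)
    fp <- mrf_fit(d, cv, method = "pseudolikelihood", penalty = 1e-6)
    ut <- upper.tri(truth$beta)
    max(abs(coef(fe)$beta[ut] - coef(fp)$beta[ut]))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("degenerate species trigger warnings and NA-marked rows", {
  set.seed(5)
  Y <- cbind(rbinom(200, 1, 0.5), rbinom(200, 1, 0.5), 1)
  d <- community_matrix(Y, species_names = c("a", "b", "always"))
  expect_warning(fe <- mrf_fit(d, NULL, method = "exact"), "prevalence")
  expect_true(is.finite(fe$final_objective))
  expect_warning(fp <- mrf_fit(d, NULL, method = "pseudolikelihood"),
                 "prevalence")
  expect_true(all(is.na(coef(fp)$beta["always", c("a", "b")])))
  expect_false(anyNA(coef(fp)$beta["a", "b"]))
})

test_that("poisson node models recover independent count structure", {
  set.seed(61)
  Y <- matrix(rpois(3 * 2000, 5), 2000, 3)
  d <- community_matrix(Y)
  f <- suppressWarnings(mrf_fit(d, NULL, method = "poisson"))
  # alpha intercept near log 5; beta near 0
  expect_equal(unname(coef(f)$alpha[, 1]), rep(log(5), 3), tolerance = 0.1)
  expect_lt(max(abs(coef(f)$beta[upper.tri(coef(f)$beta)])), 0.01)
  # negbin on equidispersed data: large dispersion parameter = no overdispersion
  fn <- mrf_fit(d, NULL, method = "negbin")
  expect_true(all(fn$dispersion > 10))
})

test_that("count-model conditional means are invariant to covariate rescaling", {
  set.seed(62)
  Y <- matrix(rpois(2 * 300, 3), 300, 2)
  d <- community_matrix(Y)
  cv1 <- covariate_matrix(cbind(intercept = 1, moist = runif(300)))
  cv2 <- covariate_matrix(cbind(intercept = 1, moist = 2 * unclass(cv1)[, 2]),
                          site_ids = rownames(cv1))
  f1 <- suppressWarnings(mrf_fit(d, cv1, method = "poisson"))
  f2 <- suppressWarnings(mrf_fit(d, cv2, method = "poisson"))
  expect_equal(coef(f2)$alpha[, "moist"], coef(f1)$alpha[, "moist"] / 2,
               tolerance = 1e-6)
  expect_equal(predict(f2, d, cv2), predict(f1, d, cv1), tolerance = 1e-6)
})

test_that("all-zero abundance species are dropped with a record", {
  Y <- cbind(rpois(100, 2), 0, rpois(100, 2))
  d <- community_matrix(Y, species_names = c("a", "zero", "b"))
  expect_warning(f <- mrf_fit(d, NULL, method = "poisson"), "all-zero")
  expect_identical(f$dropped_species, "zero")
  expect_true(all(is.na(coef(f)$beta["zero", c("a", "b")])))
})

test_that("method/mode mismatches are explicit errors", {
  occ <- community_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  ab <- community_matrix(matrix(c(0, 2, 1, 0), 2, 2))
  expect_error(mrf_fit(ab, NULL, method = "exact"), "occurrence")
  expect_error(mrf_fit(occ, NULL, method = "poisson"), "abundance")
})

test_that("fit serialization writes alpha/beta CSVs and a JSON sidecar", {
  sc <- make_nurse_scenario(n_nurse_sites = 60, n_open_sites = 60, seed = 8)
  f <- mrf_fit(sc$data, sc$covars, method = "exact")
  dir <- withr::local_tempdir()
  write_fit(f, dir)
  a <- utils::read.csv(file.path(dir, "alpha.csv"))
  expect_equal(a$species, f$params$species_names)
  expect_equal(as.matrix(a[, -1]), unname(f$params$alpha), ignore_attr = TRUE)
  js <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_identical(js$method, "exact_ml")
})
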
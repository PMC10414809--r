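# Fixed-margin null models and permutation screening.

test_that("curveball permutations preserve both margins exactly", {
  pr <- random_params(6, seed = 12, scale = 0.5)
  d <- gibbs_sample(pr, intercept_covars(40), seed = 13)
  perms <- permute_fixed_margins(d, 50, seed = 14)
  for (p in perms) {
    expect_identical(rowSums(p), rowSums(d))
    expect_identical(colSums(p), colSums(d))
  }
})

test_that("stratified permutations preserve margins per stratum", {
  pr <- random_params(5, seed = 15, scale = 0.5)
  d <- gibbs_sample(pr, intercept_covars(60), seed = 16)
  strata <- rep(c("A", "B"), each = 30)
  perms <- permute_fixed_margins(d, 30, seed = 17, strata = strata)
  for (p in perms) {
    expect_identical(rowSums(p), rowSums(d))
    for (s in c("A", "B")) {
      expect_identical(colSums(p[strata == s, ]), colSums(d[strata == s, ]))
    }
  }
})

test_that("the 2x2 checkerboard swaps between its two margin-states", {
  d <- community_matrix(rbind(c(1, 0), c(0, 1)))
  perms <- permute_fixed_margins(d, 200, seed = 18, thin = 3)
  states <- vapply(perms, function(p) paste(as.vector(p), collapse = ""), "")
  expect_true(all(states %in% c("1001", "0110")))
  expect_length(unique(states), 2)
})

test_that("a margin-unique matrix is returned unchanged with a warning", {
  d <- community_matrix(rbind(c(1, 1), c(0, 0)))
  expect_warning(perms <- permute_fixed_margins(d, 10, seed = 19),
                 "no rearrangement")
  for (p in perms) expect_equal(unclass(p)[, ], unclass(d)[, ])
})

test_that("permutation draws cover the margin class roughly uniformly", {
  # 3x3 with margins (2,1,1)/(2,1,1): small enumerable class; a chi-square
  # on visit counts should not reject wildly
  d <- community_matrix(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1)))
  perms <- permute_fixed_margins(d, 600, seed = 20, thin = 20)
  states <- vapply(perms, function(p) paste(as.vector(p), collapse = ""), "")
  tab <- table(states)
  expect_gte(length(tab), 3)               # visits more than one state
  chi <- sum((tab - 600 / length(tab))^2 / (600 / length(tab)))
  expect_lt(chi, 3 * length(tab))          # no gross non-uniformity
})

test_that("screening statistics behave: p floor, q >= p, determinism", {
  sc <- make_nurse_scenario(n_nurse_sites = 120, n_open_sites = 120, seed = 21)
  s1 <- screen_beta(sc$data, sc$covars, fit_method = "exact",
                    n_permutations = 99, seed = 22)
  s2 <- screen_beta(sc$data, sc$covars, fit_method = "exact",
                    n_permutations = 99, seed = 22)
  expect_identical(s1$p_values, s2$p_values)
  df <- as.data.frame(s1)
  expect_true(all(df$p >= 1 / 100))
  expect_true(all(df$p <= 1))
  expect_true(all(df$q >= df$p - 1e-12))
  expect_identical(s1$z_scores, t(s1$z_scores))
})

test_that("a strong negative pair is detected as significant-negative", {
  sc <- make_nurse_scenario(seed = 23)       # 500 sites, beta(Sub1,Sub2) = -1
  s <- screen_beta(sc$data, sc$covars, fit_method = "exact",
                   n_permutations = 199, seed = 24)
  df <- as.data.frame(s)
  row <- df[df$species_i == "Sub1" & df$species_j == "Sub2", ]
  expect_true(row$significant)
  expect_lt(row$beta_obs, 0)
  expect_lt(row$z, 0)
})

test_that("alpha screening flags true microhabitat effects with right signs", {
  sc <- make_nurse_scenario(seed = 25)
  s <- screen_alpha(sc$data, sc$covars, fit_method = "exact",
                    n_permutations = 99, seed = 26)
  df <- as.data.frame(s)
  nurse <- df[df$factor == "nurse", ]
  expect_true(all(nurse$significant))
  expect_equal(sign(nurse$alpha_obs[match(c("Sub1", "Sub2", "Sub3"),
                                          nurse$species)]), c(1, 1, -1))
})

test_that("screen results serialize to long-format CSV", {
  sc <- make_nurse_scenario(n_nurse_sites = 80, n_open_sites = 80, seed = 27)
  s <- screen_beta(sc$data, sc$covars, fit_method = "exact",
                   n_permutations = 99, seed = 28)
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(s, f)
  back <- utils::read.csv(f)
  expect_identical(names(back),
                   c("species_i", "species_j", "beta_obs", "z", "p", "q",
                     "significant"))
  expect_equal(nrow(back), 3)
})
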
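# Coupled community-environment dynamics: closed forms, RK4 order,
# decoupling, equilibria, and an independent ODE-solver cross-check.

test_that("exponential, logistic and linear-environment limits are exact", {
  sp <- dynamics_spec(r = 0.1, B = matrix(0, 1, 1))
  tr <- simulate_dynamics(sp, N0 = 1, t_max = 10, dt = 0.01)
  expect_equal(unname(tr$N[nrow(tr$N), 1]), exp(1), tolerance = 1e-6)

  sp2 <- dynamics_spec(r = 1, B = matrix(-1, 1, 1))
  tr2 <- simulate_dynamics(sp2, N0 = 0.01, t_max = 15, dt = 0.01)
  logistic <- function(t, n0) 1 / (1 + (1 / n0 - 1) * exp(-t))
  expect_equal(unname(tr2$N[nrow(tr2$N), 1]), logistic(15, 0.01), tolerance = 1e-6)

  sp3 <- dynamics_spec(r = 0, B = matrix(0, 1, 1), A = matrix(0, 1, 1),
                       gamma = matrix(0, 1, 1), K_drive = 0.5)
  tr3 <- simulate_dynamics(sp3, N0 = 1, E0 = 0, t_max = 10, dt = 0.01)
  expect_equal(tr3$E[, 1], 0.5 * tr3$times, tolerance = 1e-9)
})

test_that("halving the step changes the endpoint by < 1e-5 relative", {
  set.seed(40)
  B <- matrix(rnorm(9, 0, 0.1), 3, 3); diag(B) <- -1
  A <- matrix(c(0.2, -0.1, 0.05), 3, 1)
  g <- matrix(c(0.01, 0.02, -0.01), 1, 3)
  sp <- dynamics_spec(r = c(0.5, 0.4, 0.3), B = B, A = A, gamma = g,
                      K_drive = 0.1)
  end <- function(dt) {
    tr <- simulate_dynamics(sp, N0 = c(0.2, 0.3, 0.1), E0 = 0.5,
                            t_max = 20, dt = dt)
    c(tr$N[nrow(tr$N), ], tr$E[nrow(tr$E), ])
  }
  e1 <- end(0.01); e2 <- end(0.005)
  expect_lt(max(abs(e1 - e2) / pmax(abs(e2), 1e-8)), 1e-5)
})

test_that("trajectories agree with an independent adaptive ODE solver", {
  B <- matrix(c(-1, -0.3, -0.2, -1), 2, 2)
  A <- matrix(c(0.5, -0.5), 2, 1)
  g <- matrix(c(0.05, -0.02), 1, 2)
  sp <- dynamics_spec(r = c(0.8, 0.6), B = B, A = A, gamma = g, K_drive = 0.02)
  tr <- simulate_dynamics(sp, N0 = c(0.3, 0.4), E0 = 1, t_max = 25, dt = 0.01)
  ode_fun <- function(t, y, parms) {
    N <- y[1:2]; E <- y[3]
    list(c(N * (c(0.8, 0.6) + B %*% N + A %*% E), 0.02 + g %*% N))
  }
  ref <- deSolve::ode(c(0.3, 0.4, 1), c(0, 25), ode_fun, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(tr$N[nrow(tr$N), ]), unname(ref[2, 2:3]),
               tolerance = 1e-6)
  expect_equal(unname(tr$E[nrow(tr$E), 1]), unname(ref[2, 4]),
               tolerance = 1e-6)
})

test_that("abundances never go negative; extinct species stay extinct", {
  B <- matrix(c(-1, -3, -3, -1), 2, 2)          # strong mutual exclusion
  sp <- dynamics_spec(r = c(1, 0.2), B = B)
  tr <- simulate_dynamics(sp, N0 = c(1, 1e-8), t_max = 40, dt = 0.01)
  expect_true(all(tr$N >= 0))
  i_ext <- which(tr$N[, 2] == 0)[1]
  expect_true(all(tr$N[i_ext:nrow(tr$N), 2] == 0))
})

test_that("with gamma = 0 the environment decouples from the community", {
  A <- matrix(1, 1, 1)
  sp <- dynamics_spec(r = 0.5, B = matrix(-1, 1, 1), A = A,
                      gamma = matrix(0, 1, 1), K_drive = 0.1)
  tr1 <- simulate_dynamics(sp, N0 = 0.1, E0 = 0, t_max = 5, dt = 0.01)
  tr2 <- simulate_dynamics(sp, N0 = 0.9, E0 = 0, t_max = 5, dt = 0.01)
  expect_identical(tr1$E, tr2$E)
})

test_that("blow-up is flagged as divergence, not an error", {
  sp <- dynamics_spec(r = 5, B = matrix(5, 1, 1))   # super-exponential growth
  tr <- simulate_dynamics(sp, N0 = 1, t_max = 50, dt = 0.1)
  expect_true(tr$diverged)
  expect_lt(max(tr$times), 50)
  expect_true(all(is.finite(tr$N)))
})

test_that("rescaling maps beta signs onto B and alpha onto A", {
  pr <- random_params(4, K = 2, seed = 44)
  sp <- rescale_from_mrf(pr, beta_scale = 0.2, alpha_scale = 0.3,
                         self_regulation = 1.5)
  off <- !diag(4)
  expect_equal(sign(sp$B[off]), sign(pr$beta[off]))
  expect_equal(sp$B[off], 0.2 * pr$beta[off])
  expect_equal(unname(diag(sp$B)), rep(-1.5, 4))
  expect_equal(unclass(sp$A), unclass(0.3 * pr$alpha), ignore_attr = TRUE)
  # zero params give pure self-regulation
  z <- rescale_from_mrf(mrf_params(matrix(0, 2, 1), matrix(0, 2, 2)),
                        self_regulation = 2)
  expect_equal(unname(z$B), -2 * diag(2))
  expect_true(all(z$A == 0))
})

test_that("equilibria: logistic case, weak competition, infeasible case", {
  sp1 <- dynamics_spec(r = 1, B = matrix(-0.5, 1, 1))
  eq1 <- equilibria(sp1)
  expect_equal(unname(eq1$N_star), 2)
  expect_true(eq1$feasible && eq1$stable)

  B <- matrix(c(-1, -0.3, -0.3, -1), 2, 2)      # classical weak competition
  eq2 <- equilibria(dynamics_spec(r = c(1, 1), B = B))
  expect_true(eq2$feasible && eq2$stable)
  expect_equal(unname(eq2$N_star), rep(1 / 1.3, 2), tolerance = 1e-12)

  eq3 <- equilibria(dynamics_spec(r = c(-1, -1), B = B))
  expect_false(eq3$feasible)

  eq4 <- equilibria(dynamics_spec(r = 1, B = matrix(0, 1, 1)))
  expect_true(eq4$singular)
})

test_that("nurse habitat sustains facilitated species relative to open", {
  sc <- make_nurse_scenario(seed = 45)
  fit <- mrf_fit(sc$data, sc$covars, method = "exact")
  sp <- rescale_from_mrf(fit, r = rep(0.1, 3))
  run <- function(habitat) {
    ef <- if (habitat == "nurse") c(1, 0) else c(0, 1)
    tr <- simulate_dynamics(sp, N0 = rep(0.1, 3), t_max = 100, dt = 0.05,
                            E_fixed = ef)
    tr$N[nrow(tr$N), ]
  }
  n_end <- run("nurse"); o_end <- run("open")
  expect_gt(n_end[["Sub1"]], o_end[["Sub1"]])
  expect_gt(n_end[["Sub2"]], o_end[["Sub2"]])
  expect_lt(n_end[["Sub3"]], o_end[["Sub3"]])
})

test_that("trajectory CSV is tidy and round-trips", {
  sp <- dynamics_spec(r = 0.5, B = matrix(-1, 1, 1), A = matrix(0.1, 1, 1),
                      gamma = matrix(0.01, 1, 1), K_drive = 0)
  tr <- simulate_dynamics(sp, N0 = 0.1, E0 = 1, t_max = 2, dt = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("time", "variable", "type", "value"))
  expect_setequal(unique(back$type), c("species", "factor"))
  expect_equal(nrow(back), 2 * length(tr$times))
})
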
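# Coupled plant-environment dynamics:
#   dN_i/dt = N_i ( r_i + sum_j B_ij N_j ) + f(A_i, k) N_i
#   dE_k/dt = f(K) + f(gamma_ki) N_i
# with the unspecified couplings taken linear in their arguments:
#   f(A_i, k) = sum_k A_ik E_k,  f(K) = K_drive (constant),
#   f(gamma_ki) N_i = sum_i gamma_ki N_i.

#' Specify a coupled community-environment dynamical system
#'
#' Collects growth rates, the species interaction matrix (including
#' diagonal self-regulation), the rescaled environment effects, and the
#' species-on-environment feedback into one validated object.
#'
#' @param r per-species intrinsic growth rates (1/time).
#' @param B species x species interaction matrix: per-unit-abundance effect
#'   of species j on i; diagonal entries are self-regulation.
#' @param A species x factors matrix of environment effects on growth
#'   (default none: zero factors).
#' @param gamma factors x species matrix: per-unit-abundance effect of each
#'   species on each environmental factor (default zero).
#' @param K_drive per-factor constant baseline forcing (factor units /
#'   time; default zero).
#' @param E_clip optional factors x 2 matrix of `[min, max]` bounds applied
#'   to the environment state after every step (e.g. a moisture fraction);
#'   default unbounded.
#' @param extinction abundance below which a species is clamped to 0.
#' @param species_names,factor_names labels.
#' @return an object of class `dynamics_spec`.
#' @seealso [simulate_dynamics()], [rescale_from_mrf()], [equilibria()]
#' @export
dynamics_spec <- function(r, B, A = NULL, gamma = NULL, K_drive = NULL,
                          E_clip = NULL, extinction = 1e-9,
                          species_names = NULL, factor_names = NULL) {
  r <- as.numeric(r)
  S <- length(r)
  B <- as.matrix(B)
  if (!all(dim(B) == c(S, S))) stop_dims("B", dim(B), c(S, S))
  K <- if (!is.null(A)) ncol(as.matrix(A))
       else if (!is.null(gamma)) nrow(as.matrix(gamma))
       else length(K_drive %||% numeric(0))
  A <- if (is.null(A)) matrix(0, S, K) else as.matrix(A)
  gamma <- if (is.null(gamma)) matrix(0, K, S) else as.matrix(gamma)
  K_drive <- as.numeric(K_drive %||% rep(0, K))
  if (!all(dim(A) == c(S, K))) stop_dims("A", dim(A), c(S, K))
  if (!all(dim(gamma) == c(K, S))) stop_dims("gamma", dim(gamma), c(K, S))
  if (length(K_drive) != K) stop_dims("K_drive", length(K_drive), K)
  if (!is.null(E_clip)) {
    E_clip <- as.matrix(E_clip)
    if (!all(dim(E_clip) == c(K, 2))) stop_dims("E_clip", dim(E_clip), c(K, 2))
  }
  species_names <- as.character(species_names %||% rownames(B) %||%
                                  paste0("sp_", seq_len(S)))
  factor_names <- as.character(factor_names %||% colnames(A) %||%
                                 if (K) paste0("f_", seq_len(K)) else character(0))
  dimnames(B) <- list(species_names, species_names)
  if (K) { dimnames(A) <- list(species_names, factor_names)
           dimnames(gamma) <- list(factor_names, species_names) }
  structure(list(r = stats::setNames(r, species_names), B = B, A = A,
                 gamma = gamma, K_drive = K_drive, E_clip = E_clip,
                 extinction = extinction, env_coupling = "linear",
                 species_names = species_names, factor_names = factor_names),
            class = "dynamics_spec")
}

#' @export
print.dynamics_spec <- function(x, ...) {
  cat(sprintf("dynamics_spec: %d species, %d environmental factors\n",
              length(x$r), length(x$factor_names)))
  cat("  r:", paste(signif(x$r, 4), collapse = ", "), "\n")
  cat("  self-regulation (diag B):", paste(signif(diag(x$B), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Rescale fitted Markov network parameters into a dynamical system
#'
#' Maps the statistical association scale onto per-unit-abundance dynamical
#' effects: `B_ij = beta_scale * beta_ij` for i != j, `B_ii =
#' -self_regulation`, and `A = alpha_scale * alpha`. Off-diagonal signs of
#' `B` therefore equal the signs of `beta`. The scales are free parameters
#' -- the occurrence model carries no abundance units -- and their defaults
#' (`0.1`, `0.1`, `1.0`) are assumptions to be revisited per system.
#'
#' @param params an [mrf_params()] or [mrf_fit()].
#' @param beta_scale,alpha_scale positive multipliers taking beta and alpha
#'   to dynamical units.
#' @param self_regulation magnitude of the (negative) diagonal of `B`.
#' @param r per-species intrinsic growth rates (default 0.1 for all).
#' @param gamma,K_drive,E_clip forwarded to [dynamics_spec()].
#' @return a [dynamics_spec()].
#' @export
rescale_from_mrf <- function(params, beta_scale = 0.1, alpha_scale = 0.1,
                             self_regulation = 1.0, r = NULL, gamma = NULL,
                             K_drive = NULL, E_clip = NULL) {
  if (inherits(params, "mrf_fit")) params <- params$params
  stopifnot(beta_scale > 0, alpha_scale > 0, self_regulation >= 0)
  beta <- params$beta; beta[is.na(beta)] <- 0
  alpha <- params$alpha; alpha[is.na(alpha)] <- 0
  B <- beta_scale * beta
  diag(B) <- -self_regulation
  A <- alpha_scale * alpha
  S <- n_species(params)
  dynamics_spec(r = r %||% rep(0.1, S), B = B, A = A, gamma = gamma,
                K_drive = K_drive, E_clip = E_clip,
                species_names = params$species_names,
                factor_names = params$factor_names)
}

#' Integrate the coupled plant-environment system
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the community
#' and environment equations, chosen over adaptive schemes for exact
#' reproducibility. After every step species below the extinction
#' threshold are clamped to zero and the environment is clipped to
#' `E_clip` bounds if given. A non-finite state stops the integration
#' early and flags the trajectory as diverged instead of erroring.
#'
#' @param spec a [dynamics_spec()].
#' @param N0 initial abundances/cover (non-negative, length S).
#' @param E0 initial environment state (length = factor count).
#' @param t_max end time (> 0).
#' @param dt step size (> 0); default 0.01.
#' @param record_every record every k-th step (thinning); default 1.
#' @param E_fixed optional per-factor values held constant throughout
#'   (overrides the environment equation; useful for microhabitat
#'   indicator factors).
#' @return an object of class `cn_trajectory`: `times`, matrix `N`
#'   (time x species), matrix `E` (time x factors), and a `diverged` flag.
#' @examples
#' sp <- dynamics_spec(r = 1, B = matrix(-1, 1, 1))
#' tr <- simulate_dynamics(sp, N0 = 0.01, t_max = 20)
#' tail(tr$N, 1)  # logistic equilibrium r/|B| = 1
#' @export
simulate_dynamics <- function(spec, N0, E0 = NULL, t_max, dt = 0.01,
                              record_every = 1L, E_fixed = NULL) {
  stopifnot(inherits(spec, "dynamics_spec"), dt > 0, t_max > 0, all(N0 >= 0))
  S <- length(spec$r)
  K <- length(spec$factor_names)
  if (length(N0) != S) stop_dims("N0", length(N0), S)
  E0 <- as.numeric(E0 %||% rep(0, K))
  if (length(E0) != K) stop_dims("E0", length(E0), K)
  if (!is.null(E_fixed)) {
    if (length(E_fixed) != K) stop_dims("E_fixed", length(E_fixed), K)
    E0 <- as.numeric(E_fixed)
  }
  r <- as.numeric(spec$r); B <- spec$B; A <- spec$A
  gamma <- spec$gamma; Kd <- spec$K_drive
  deriv <- function(N, E) {
    dN <- N * (r + drop(B %*% N) + if (K) drop(A %*% E) else 0)
    dE <- if (K && is.null(E_fixed)) Kd + drop(gamma %*% N) else numeric(K)
    list(dN = dN, dE = dE)
  }
  n_steps <- ceiling(t_max / dt - 1e-9)
  rec <- seq(0L, n_steps, by = record_every)
  if (rec[length(rec)] != n_steps) rec <- c(rec, n_steps)
  Nrec <- matrix(NA_real_, length(rec), S,
                 dimnames = list(NULL, spec$species_names))
  Erec <- matrix(NA_real_, length(rec), K,
                 dimnames = list(NULL, spec$factor_names))
  N <- as.numeric(N0); E <- E0
  Nrec[1, ] <- N; if (K) Erec[1, ] <- E
  ri <- 2L
  diverged <- FALSE
  for (step in seq_len(n_steps)) {
    h <- min(dt, t_max - (step - 1) * dt)
    k1 <- deriv(N, E)
    k2 <- deriv(N + h / 2 * k1$dN, E + h / 2 * k1$dE)
    k3 <- deriv(N + h / 2 * k2$dN, E + h / 2 * k2$dE)
    k4 <- deriv(N + h * k3$dN, E + h * k3$dE)
    N <- N + h / 6 * (k1$dN + 2 * k2$dN + 2 * k3$dN + k4$dN)
    E <- E + h / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
    N[N < spec$extinction] <- 0
    if (!is.null(spec$E_clip) && K) {
      E <- pmin(pmax(E, spec$E_clip[, 1]), spec$E_clip[, 2])
    }
    if (any(!is.finite(N)) || any(!is.finite(E))) { diverged <- TRUE; break }
    if (ri <= length(rec) && step == rec[ri]) {
      Nrec[ri, ] <- N; if (K) Erec[ri, ] <- E
      ri <- ri + 1L
    }
  }
  keep <- seq_len(ri - 1L)
  structure(list(times = pmin(rec[keep] * dt, t_max), N = Nrec[keep, , drop = FALSE],
                 E = Erec[keep, , drop = FALSE], diverged = diverged,
                 dt = dt, spec = spec),
            class = "cn_trajectory")
}

#' @export
print.cn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d recorded times over [0, %g]%s\n",
              length(x$times), max(x$times),
              if (x$diverged) " (DIVERGED, truncated)" else ""))
  cat("final N:", paste(signif(x$N[nrow(x$N), ], 4), collapse = ", "), "\n")
  if (ncol(x$E)) cat("final E:", paste(signif(x$E[nrow(x$E), ], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#' @param x a `cn_trajectory`.
#' @param ... unused.
#' @return data.frame with columns `time`, `variable`, `type`
#'   (`species` / `factor`), `value`.
#' @export
as.data.frame.cn_trajectory <- function(x, ...) {
  sp <- data.frame(time = rep(x$times, ncol(x$N)),
                   variable = rep(colnames(x$N), each = length(x$times)),
                   type = "species", value = as.vector(x$N))
  if (ncol(x$E)) {
    en <- data.frame(time = rep(x$times, ncol(x$E)),
                     variable = rep(colnames(x$E), each = length(x$times)),
                     type = "factor", value = as.vector(x$E))
    sp <- rbind(sp, en)
  }
  sp
}

#' Write a trajectory as tidy CSV
#' @param x a `cn_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.cn_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$N, type = "l", lty = 1, lwd = 2,
                    xlab = "time", ylab = "abundance / cover",
                    main = "community dynamics", ...)
  graphics::legend("topright", colnames(x$N), col = seq_len(ncol(x$N)),
                   lty = 1, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Interior community equilibrium at fixed environment
#'
#' Solves `r + A E + B N* = 0` for the community state at a fixed
#' environment, and reports feasibility (all `N* > 0`) and local stability
#' from the eigenvalues of the community Jacobian
#' `J_ij = N*_i B_ij` evaluated at the interior equilibrium.
#'
#' @param spec a [dynamics_spec()].
#' @param E_fixed per-factor environment values (default all zero).
#' @return a list: `N_star`, `feasible`, `stable`, `eigenvalues`,
#'   `singular` (TRUE when `B` is not invertible; no equilibrium returned).
#' @export
equilibria <- function(spec, E_fixed = NULL) {
  stopifnot(inherits(spec, "dynamics_spec"))
  K <- length(spec$factor_names)
  E_fixed <- as.numeric(E_fixed %||% rep(0, K))
  if (length(E_fixed) != K) stop_dims("E_fixed", length(E_fixed), K)
  b <- as.numeric(spec$r) + if (K) drop(spec$A %*% E_fixed) else 0
  Ns <- tryCatch(solve(spec$B, -b), error = function(e) NULL)
  if (is.null(Ns)) {
    return(list(N_star = NULL, feasible = FALSE, stable = NA,
                eigenvalues = NULL, singular = TRUE))
  }
  names(Ns) <- spec$species_names
  J <- Ns * spec$B                      # row-scale: J_ij = N*_i B_ij
  ev <- eigen(J, only.values = TRUE)$values
  list(N_star = Ns, feasible = all(Ns > 0),
       stable = max(Re(ev)) < 0, eigenvalues = ev, singular = FALSE)
}
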
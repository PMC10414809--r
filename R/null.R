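# Null-model screening: inferred associations are only hypotheses about
# interaction outcomes, so every link is compared against a permutation
# null before it enters a constructive network.

#' Fixed-margin (curveball) permutations of an occurrence matrix
#'
#' Generates null community matrices preserving every site richness (row
#' sum) and species prevalence (column sum) exactly, via the curveball
#' trade algorithm as implemented in \pkg{vegan}. Fixing both margins
#' separates environmentally driven prevalence structure (captured by
#' `alpha`) from the pairwise association structure being tested.
#'
#' When `strata` is given (one label per site, typically the microhabitat),
#' trades are confined within strata, so each species' prevalence is
#' preserved *per stratum* rather than only overall. This keeps
#' environment-driven prevalence structure out of the null distribution of
#' `beta` -- without stratification, species that share or oppose habitat
#' preferences acquire spurious association signal relative to a null that
#' scrambles them across habitats. Row and column sums of the full matrix
#' are exactly preserved either way.
#'
#' @param data an occurrence-mode [community_matrix()].
#' @param n_permutations number of null matrices.
#' @param seed integer seed (bit-for-bit reproducible draws).
#' @param thin curveball trades between successive draws; default
#'   `5 * sum(data)` (five times the matrix fill, counted per stratum).
#' @param strata optional vector of site labels; trades stay within a
#'   stratum.
#' @return a list of `n_permutations` [community_matrix()] objects.
#' @export
permute_fixed_margins <- function(data, n_permutations, seed = NULL, thin = NULL,
                                  strata = NULL) {
  if (community_mode(data) != "occurrence") {
    stop("fixed-margin permutation is defined for occurrence matrices", call. = FALSE)
  }
  m <- unclass(data)
  strata <- strata %||% rep(1L, nrow(m))
  if (length(strata) != nrow(m)) stop_dims("strata", length(strata), nrow(m))
  groups <- split(seq_len(nrow(m)), strata)
  sims_by_group <- with_seed(seed, lapply(groups, function(g) {
    sub <- m[g, , drop = FALSE]
    if (length(g) < 2L || sum(sub) == 0) {
      return(array(sub, c(dim(sub), n_permutations)))
    }
    th <- as.integer(thin %||% max(1, 5 * sum(sub)))
    nm <- vegan::nullmodel(sub, "curveball")
    stats::simulate(nm, nsim = n_permutations, thin = th, burnin = th,
                    seed = sample.int(.Machine$integer.max, 1))
  }))
  out <- lapply(seq_len(n_permutations), function(k) {
    perm <- m
    for (j in seq_along(groups)) {
      perm[groups[[j]], ] <- sims_by_group[[j]][, , k]
    }
    community_matrix(perm, site_ids = rownames(m),
                     species_names = colnames(m), mode = "occurrence")
  })
  if (all(vapply(out, function(p) all(p == m), logical(1)))) {
    warning("matrix margins admit no rearrangement; permutations equal the input",
            call. = FALSE)
  }
  out
}

# shared permutation-screen core: obs and nulls are numeric matrices of the
# same shape (beta SxS or alpha SxK); returns mean/sd/z/p over the entries
# indexed by `sel` (a logical matrix marking the tested entries)
perm_screen_stats <- function(obs, nulls, sel) {
  arr <- simplify2array(nulls)
  m <- length(nulls)
  null_mean <- apply(arr, c(1, 2), mean)
  null_sd <- apply(arr, c(1, 2), stats::sd)
  z <- (obs - null_mean) / null_sd
  z[!is.finite(z)] <- 0
  dev_obs <- abs(obs - null_mean)
  exceed <- Reduce(`+`, lapply(seq_len(m), function(k) {
    (abs(arr[, , k] - null_mean) >= dev_obs - 1e-12) * 1
  }))
  p <- (exceed + 1) / (m + 1)
  p[is.na(obs)] <- NA_real_
  q <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  q[sel] <- stats::p.adjust(p[sel], method = "BH")
  list(null_mean = null_mean, null_sd = null_sd, z = z, p = p, q = q)
}

new_screen <- function(layer, obs, st, n_perm, n_failed, method, fdr, seed) {
  structure(list(layer = layer, observed = obs,
                 null_mean = st$null_mean, null_sd = st$null_sd,
                 z_scores = st$z, p_values = st$p, q_values = st$q,
                 n_permutations = n_perm, n_failed = n_failed,
                 unreliable = n_failed > 0.1 * n_perm,
                 method = method, fdr = fdr, seed = seed),
            class = "mrf_screen")
}

refit_params <- function(data, covars, fit_method, penalty) {
  f <- suppressWarnings(mrf_fit(data, covars, method = fit_method,
                                penalty = penalty))
  f$params
}

#' Screen species-species associations against a fixed-margin null
#'
#' Refits the Markov network on curveball permutations of the community
#' matrix (same covariates throughout) and compares each observed
#' `beta_ij` with its null distribution: `z = (observed - null mean) /
#' null sd`, a two-sided permutation p-value with the `(b + 1)/(m + 1)`
#' correction, and Benjamini-Hochberg q-values across the `S(S-1)/2`
#' unordered pairs.
#'
#' When the covariates are categorical (few distinct covariate rows, e.g.
#' one-hot microhabitats), permutations are stratified by covariate row so
#' the null preserves each species' prevalence per microhabitat -- the
#' environmental structure belongs to `alpha` and must not contaminate the
#' `beta` null (see [permute_fixed_margins()]). With effectively continuous
#' covariates (more than `max_strata` distinct rows) the global
#' fixed-margin null is used.
#'
#' @param data an occurrence-mode [community_matrix()].
#' @param covars a [covariate_matrix()] or `NULL` (intercept only).
#' @param fit_method `"pseudolikelihood"` (default) or `"exact"`.
#' @param n_permutations number of null refits (>= 99).
#' @param fdr nominal false-discovery rate for the `significant` column of
#'   [as.data.frame.mrf_screen()].
#' @param seed integer seed.
#' @param penalty ridge penalty forwarded to [mrf_fit()].
#' @param thin curveball thinning, see [permute_fixed_margins()].
#' @param max_strata stratify the null by distinct covariate rows when
#'   there are at most this many (default 10).
#' @return an object of class `mrf_screen` with symmetric matrices
#'   `observed`, `null_mean`, `null_sd`, `z_scores`, `p_values`,
#'   `q_values`, plus counts of permutations and failed refits (the result
#'   is flagged `unreliable` when more than 10\% fail).
#' @seealso [screen_alpha()], [build_network()]
#' @export
screen_beta <- function(data, covars = NULL,
                        fit_method = c("pseudolikelihood", "exact"),
                        n_permutations = 199L, fdr = 0.05, seed = NULL,
                        penalty = 1e-3, thin = NULL, max_strata = 10L) {
  fit_method <- match.arg(fit_method)
  stopifnot(n_permutations >= 99L)
  covars <- align_covariates(data, covars)
  obs <- refit_params(data, covars, fit_method, penalty)$beta
  key <- apply(unclass(covars), 1, paste, collapse = "\r")
  strata <- if (length(unique(key)) <= max_strata) key else NULL
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2))
  perms <- permute_fixed_margins(data, n_permutations, seed = seeds[1],
                                 thin = thin, strata = strata)
  nulls <- lapply(perms, function(p) {
    tryCatch(refit_params(p, covars, fit_method, penalty)$beta,
             error = function(e) NULL)
  })
  failed <- sum(vapply(nulls, is.null, logical(1)))
  nulls <- Filter(Negate(is.null), nulls)
  if (!length(nulls)) stop("all permutation refits failed", call. = FALSE)
  st <- perm_screen_stats(obs, nulls, upper.tri(obs))
  new_screen("beta", obs, st, length(nulls), failed, fit_method, fdr, seed)
}

#' Screen species-environment effects by site-label permutation
#'
#' Fixed-margin permutation leaves the covariates untouched, so `alpha`
#' effects are screened differently: the covariate rows are permuted
#' across sites (breaking the species-environment pairing while keeping
#' both marginal structures) and the model refitted on each draw.
#'
#' @inheritParams screen_beta
#' @return an `mrf_screen` (layer `"alpha"`) whose matrices are species x
#'   factors.
#' @export
screen_alpha <- function(data, covars,
                         fit_method = c("pseudolikelihood", "exact"),
                         n_permutations = 199L, fdr = 0.05, seed = NULL,
                         penalty = 1e-3) {
  fit_method <- match.arg(fit_method)
  stopifnot(n_permutations >= 99L)
  covars <- align_covariates(data, covars)
  obs <- refit_params(data, covars, fit_method, penalty)$alpha
  X <- unclass(covars)
  n <- nrow(X)
  shuffles <- with_seed(seed, replicate(n_permutations, sample.int(n),
                                        simplify = FALSE))
  nulls <- lapply(shuffles, function(ix) {
    cv <- covariate_matrix(X[ix, , drop = FALSE], site_ids = rownames(X),
                           factor_names = colnames(X))
    tryCatch(refit_params(data, cv, fit_method, penalty)$alpha,
             error = function(e) NULL)
  })
  failed <- sum(vapply(nulls, is.null, logical(1)))
  nulls <- Filter(Negate(is.null), nulls)
  if (!length(nulls)) stop("all permutation refits failed", call. = FALSE)
  sel <- matrix(TRUE, nrow(obs), ncol(obs))
  st <- perm_screen_stats(obs, nulls, sel)
  st$q <- matrix(stats::p.adjust(st$p, "BH"), nrow(obs), dimnames = dimnames(obs))
  new_screen("alpha", obs, st, length(nulls), failed, fit_method, fdr, seed)
}

#' @export
print.mrf_screen <- function(x, ...) {
  cat(sprintf("permutation screen (%s layer, %s fit): %d permutations",
              x$layer, x$method, x$n_permutations))
  if (x$n_failed) cat(sprintf(", %d failed refits", x$n_failed))
  cat("\n")
  if (x$unreliable) cat("  WARNING: > 10% of refits failed; result unreliable\n")
  df <- as.data.frame(x)
  cat(sprintf("  %d of %d links significant at FDR %.2f\n",
              sum(df$significant, na.rm = TRUE), nrow(df), x$fdr))
  invisible(x)
}

#' Long-format view of a permutation screen
#'
#' @param x an `mrf_screen`.
#' @param ... unused.
#' @return for the beta layer, one row per unordered species pair with
#'   columns `species_i`, `species_j`, `beta_obs`, `z`, `p`, `q`,
#'   `significant`; for the alpha layer, one row per species-factor pair
#'   (`species`, `factor`, `alpha_obs`, ...).
#' @export
as.data.frame.mrf_screen <- function(x, ...) {
  if (x$layer == "beta") {
    ut <- which(upper.tri(x$observed), arr.ind = TRUE)
    df <- data.frame(
      species_i = rownames(x$observed)[ut[, 1]],
      species_j = colnames(x$observed)[ut[, 2]],
      beta_obs = x$observed[ut], z = x$z_scores[ut],
      p = x$p_values[ut], q = x$q_values[ut])
  } else {
    grid <- expand.grid(species = rownames(x$observed),
                        factor = colnames(x$observed),
                        stringsAsFactors = FALSE)
    df <- data.frame(grid, alpha_obs = as.vector(x$observed),
                     z = as.vector(x$z_scores), p = as.vector(x$p_values),
                     q = as.vector(x$q_values))
  }
  df$significant <- !is.na(df$q) & df$q < x$fdr
  df
}

#' Write a screen result as long-format CSV
#' @param x an `mrf_screen`.
#' @param path output file.
#' @export
write_screen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
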
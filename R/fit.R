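#' Fit a Markov network to community data
#'
#' The package's central estimator. Given a site-by-species
#' [community_matrix()] and (optionally) a site-by-factor
#' [covariate_matrix()], estimates the species--environment effects `alpha`
#' and the symmetric species--species associations `beta` of the pairwise
#' Markov network
#' \deqn{p(y \mid x) \propto \exp\Big(\sum_i (\alpha_i \cdot x)\, y_i +
#'   \sum_{i<j} \beta_{ij} y_i y_j\Big).}
#'
#' Four methods are available:
#' \describe{
#'   \item{`exact`}{maximum likelihood with the exact partition function
#'     (full enumeration of the 2^S configurations; S <= 20). Newton
#'     iterations on the mean per-site log-likelihood with analytic gradient
#'     (observed minus expected sufficient statistics) and Hessian (feature
#'     covariance); convergence when the penalized gradient norm drops below
#'     `tol`.}
#'   \item{`pseudolikelihood`}{one ridge-penalized logistic regression per
#'     species, with the covariates and all other species' occupancies as
#'     predictors; the two directed neighbour coefficients of each pair are
#'     averaged into the symmetric `beta`.}
#'   \item{`poisson`, `negbin`}{node-conditional count regressions with log
#'     link for abundance data; `negbin` estimates one dispersion per
#'     species. Interpreted as conditional-association estimates (a Poisson
#'     MRF with positive beta is not normalizable; a warning is attached
#'     when any fitted beta is positive under `poisson`).}
#' }
#'
#' The ridge penalty applies to `beta` (never to `alpha`) on the scale of
#' the mean per-site objective; its default `1e-3` stabilizes sparse
#' co-occurrence tables. Species with prevalence 0 or 1 are unidentifiable
#' for `beta`: under the node-conditional methods they are excluded and
#' their rows are returned as `NA` (with a warning); under `exact` the fit
#' is ridge-penalized on all parameters instead (with a warning).
#'
#' @param data a [community_matrix()].
#' @param covars a [covariate_matrix()] aligned by site id, or `NULL` for an
#'   intercept-only design (a single all-ones factor named `"intercept"`).
#' @param method `"auto"` picks `exact` for occurrence data with S <= 10,
#'   `pseudolikelihood` for larger occurrence pools, `poisson` for
#'   abundance data.
#' @param penalty ridge penalty on beta (per-site scale).
#' @param tol gradient-norm convergence tolerance for `exact`.
#' @param max_iter iteration cap.
#' @return an object of class `mrf_fit`: a list with `params`
#'   ([mrf_params()]), `method`, `converged`, `final_objective` (mean
#'   per-site log-(pseudo)likelihood at the optimum), `n_iterations`,
#'   `standard_errors` (list of `alpha`/`beta` matrices), `penalty`,
#'   `dispersion` (negbin only), `dropped_species`, `degenerate_species`,
#'   and the aligned `data`/`covars` used.
#' @seealso [screen_beta()], [build_network()], [simulate.mrf_fit()]
#' @examples
#' sc <- make_nurse_scenario(n_nurse_sites = 100, n_open_sites = 100, seed = 1)
#' fit <- mrf_fit(sc$data, sc$covars, method = "exact")
#' coef(fit)$beta
#' @export
mrf_fit <- function(data, covars = NULL,
                    method = c("auto", "exact", "pseudolikelihood", "poisson", "negbin"),
                    penalty = 1e-3, tol = 1e-6, max_iter = 500L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "community_matrix"))
  covars <- align_covariates(data, covars)
  mode <- community_mode(data)
  if (method == "auto") {
    method <- if (mode == "abundance") "poisson"
      else if (ncol(data) <= 10L) "exact" else "pseudolikelihood"
  }
  if (method %in% c("exact", "pseudolikelihood") && mode != "occurrence") {
    stop("method '", method, "' requires occurrence data; use method = ",
         "'poisson' or 'negbin' for abundance matrices", call. = FALSE)
  }
  if (method %in% c("poisson", "negbin") && mode != "abundance") {
    stop("method '", method, "' requires abundance data", call. = FALSE)
  }
  fit <- switch(method,
    exact = fit_exact_ml(data, covars, penalty, tol, max_iter),
    pseudolikelihood = fit_pl(data, covars, penalty, max_iter),
    poisson = fit_counts(data, covars, "poisson"),
    negbin = fit_counts(data, covars, "negbin"))
  fit$call <- match.call()
  fit$data <- data
  fit$covars <- covars
  class(fit) <- "mrf_fit"
  fit
}

# ---- exact maximum likelihood --------------------------------------------

fit_exact_ml <- function(data, covars, penalty, tol, max_iter) {
  Y <- unclass(data); X <- unclass(covars)
  S <- ncol(Y); K <- ncol(X); n <- nrow(Y)
  if (n < 2L) stop("exact fitting needs at least 2 sites", call. = FALSE)
  if (S > ENUM_LIMIT) {
    stop("S = ", S, " exceeds the enumeration limit (", ENUM_LIMIT,
         "); use pseudolikelihood", call. = FALSE)
  }
  prev <- colMeans(Y)
  degenerate <- colnames(Y)[prev %in% c(0, 1)]
  P <- S * K + S * (S - 1L) / 2L
  # penalty mask: beta entries always; alpha too when data are degenerate
  pen <- c(rep(if (length(degenerate)) TRUE else FALSE, S * K),
           rep(TRUE, S * (S - 1L) / 2L))
  lam <- penalty
  if (length(degenerate)) {
    warning("species with prevalence 0 or 1 (", paste(degenerate, collapse = ", "),
            "): applying ridge penalty to all parameters", call. = FALSE)
    lam <- max(penalty, 1e-3)
  }
  C <- enum_configs(S)
  key <- apply(X, 1, paste, collapse = "\r")
  groups <- split(seq_len(n), key)
  w <- vapply(groups, length, integer(1)) / n
  Flist <- lapply(groups, function(g) config_features(C, X[g[1], ]))
  obs <- observed_stats(Y, X)

  objective <- function(theta) {
    lz <- vapply(Flist, function(Fu) logsumexp(drop(Fu %*% theta)), numeric(1))
    sum(theta * obs) - sum(w * lz) - 0.5 * lam * sum(theta[pen]^2)
  }
  theta <- numeric(P)
  obj <- objective(theta)
  iter <- 0L
  gnorm <- Inf
  repeat {
    iter <- iter + 1L
    Emean <- numeric(P)
    H <- matrix(0, P, P)
    for (u in seq_along(Flist)) {
      Fu <- Flist[[u]]
      lp <- drop(Fu %*% theta)
      p <- exp(lp - logsumexp(lp))
      Eu <- drop(crossprod(Fu, p))
      H <- H + w[u] * (crossprod(Fu, Fu * p) - tcrossprod(Eu))
      Emean <- Emean + w[u] * Eu
    }
    g <- obs - Emean - lam * ifelse(pen, theta, 0)
    gnorm <- sqrt(sum(g^2))
    if (gnorm <= tol || iter > max_iter) break
    Hpen <- H + diag(lam * pen + 1e-10, P)
    step <- tryCatch(solve(Hpen, g), error = function(e) g)  # fall back to gradient
    t_ <- 1
    repeat {
      cand <- theta + t_ * step
      ocand <- objective(cand)
      if (ocand >= obj - 1e-12 || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    theta <- theta + t_ * step
    obj <- objective(theta)
  }
  params <- unpack_params(theta, S, K, colnames(Y), colnames(X))
  # SEs from the inverse observed information of the total log-likelihood
  se <- tryCatch({
    info <- n * (H + diag(lam * pen, P))
    sqrt(diag(solve(info)))
  }, error = function(e) rep(NA_real_, P))
  sep <- unpack_params(se, S, K, colnames(Y), colnames(X))
  diag(sep$beta) <- NA_real_
  list(params = params, method = "exact_ml",
       converged = gnorm <= tol, final_objective = obj,
       n_iterations = iter, gradient_norm = gnorm,
       standard_errors = list(alpha = sep$alpha, beta = sep$beta),
       penalty = lam, degenerate_species = degenerate,
       dropped_species = character(0))
}

# ---- ridge-penalized logistic node model ---------------------------------
# Newton-Raphson on the mean negative log-likelihood with an optional ridge
# on a subset of coefficients; small, deterministic, no global state.

ridge_logit <- function(Xd, y, penalty, penalize, max_iter = 100L, tol = 1e-10) {
  n <- nrow(Xd); p <- ncol(Xd)
  D <- penalty * penalize
  b <- numeric(p)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% b)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xd, y - mu)) / n - D * b
    if (sqrt(sum(g^2)) < tol) { conv <- TRUE; break }
    Wv <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * Wv) / n + diag(D + 1e-12, p)
    step <- solve(H, g)
    # damped update: halve until the penalized objective does not decrease
    obj <- function(bb) {
      e <- drop(Xd %*% bb)
      mean(y * e - log1p(exp(e))) - 0.5 * sum(D * bb^2)
    }
    o0 <- obj(b); t_ <- 1
    while (obj(b + t_ * step) < o0 - 1e-12 && t_ > 1e-8) t_ <- t_ / 2
    b <- b + t_ * step
  }
  eta <- drop(Xd %*% b)
  ll <- sum(y * eta - log1p(exp(eta)))
  Wv <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  Hn <- crossprod(Xd, Xd * Wv) + diag(n * D + 1e-12, p)
  se <- tryCatch(sqrt(diag(solve(Hn))), error = function(e) rep(NA_real_, p))
  list(coef = b, converged = conv, iter = it, loglik = ll, se = se)
}

fit_pl <- function(data, covars, penalty, max_iter) {
  Y <- unclass(data); X <- unclass(covars)
  S <- ncol(Y); K <- ncol(X)
  if (S < 2L) stop("pseudolikelihood needs at least 2 species", call. = FALSE)
  prev <- colMeans(Y)
  degenerate <- colnames(Y)[prev %in% c(0, 1)]
  if (length(degenerate)) {
    warning("species with prevalence 0 or 1 excluded from estimation: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  ok <- !(colnames(Y) %in% degenerate)
  alpha <- matrix(NA_real_, S, K, dimnames = list(colnames(Y), colnames(X)))
  alpha_se <- alpha
  bdir <- matrix(NA_real_, S, S, dimnames = list(colnames(Y), colnames(Y)))
  bdir_se <- bdir
  total_ll <- 0
  iters <- 0L
  conv <- TRUE
  for (i in which(ok)) {
    nb <- setdiff(which(ok), i)
    Xd <- cbind(X, Y[, nb, drop = FALSE])
    penmask <- c(rep(FALSE, K), rep(TRUE, length(nb)))
    f <- ridge_logit(Xd, Y[, i], penalty, penmask, max_iter = max_iter)
    if (!f$converged || any(abs(f$coef) > 15)) {
      # separation or near-separation: refit with ridge on everything
      warning("near-separation in node model for '", colnames(Y)[i],
              "'; refitting with full ridge penalty", call. = FALSE)
      f <- ridge_logit(Xd, Y[, i], max(penalty, 1e-2), rep(TRUE, ncol(Xd)),
                       max_iter = max_iter)
    }
    alpha[i, ] <- f$coef[seq_len(K)]
    alpha_se[i, ] <- f$se[seq_len(K)]
    bdir[i, nb] <- f$coef[-seq_len(K)]
    bdir_se[i, nb] <- f$se[-seq_len(K)]
    total_ll <- total_ll + f$loglik
    iters <- max(iters, f$iter)
    conv <- conv && f$converged
  }
  beta <- (bdir + t(bdir)) / 2            # symmetrize: mean of the two directions
  beta[!ok, ] <- NA_real_; beta[, !ok] <- NA_real_
  diag(beta) <- 0
  beta_se <- sqrt((bdir_se^2 + t(bdir_se)^2)) / 2
  beta_fill <- beta; beta_fill[is.na(beta_fill)] <- 0; diag(beta_fill) <- 0
  params <- mrf_params(ifelse(is.na(alpha), 0, alpha), beta_fill,
                       colnames(Y), colnames(X))
  params$alpha[is.na(alpha)] <- NA_real_
  params$beta[is.na(beta)] <- NA_real_; diag(params$beta) <- 0
  list(params = params, method = "pseudolikelihood",
       converged = conv, final_objective = total_ll / nrow(Y),
       n_iterations = iters,
       standard_errors = list(alpha = alpha_se, beta = beta_se),
       penalty = penalty, degenerate_species = degenerate,
       dropped_species = character(0))
}

# ---- node-conditional count models (abundance) ---------------------------

fit_counts <- function(data, covars, family) {
  Y <- unclass(data); X <- unclass(covars)
  S <- ncol(Y); K <- ncol(X)
  dropped <- colnames(Y)[colSums(Y) == 0]
  if (length(dropped)) {
    warning("all-zero species dropped from estimation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  ok <- colSums(Y) > 0
  alpha <- matrix(NA_real_, S, K, dimnames = list(colnames(Y), colnames(X)))
  alpha_se <- alpha
  bdir <- matrix(NA_real_, S, S, dimnames = list(colnames(Y), colnames(Y)))
  bdir_se <- bdir
  disp <- stats::setNames(rep(NA_real_, S), colnames(Y))
  total_ll <- 0; conv <- TRUE; iters <- 0L
  for (i in which(ok)) {
    nb <- which(ok & seq_len(S) != i)
    df <- as.data.frame(cbind(X, Y[, nb, drop = FALSE]))
    names(df) <- c(paste0(".x", seq_len(K)), paste0(".n", seq_along(nb)))
    df$.y <- Y[, i]
    fml <- stats::as.formula(paste(".y ~ 0 +", paste(setdiff(names(df), ".y"),
                                                     collapse = " + ")))
    f <- if (family == "poisson") {
      suppressWarnings(stats::glm(fml, data = df, family = stats::poisson()))
    } else {
      tryCatch(suppressWarnings(MASS::glm.nb(fml, data = df)),
               error = function(e) {
                 warning("negbin fit failed for '", colnames(Y)[i],
                         "' (", conditionMessage(e), "); using poisson",
                         call. = FALSE)
                 suppressWarnings(stats::glm(fml, data = df, family = stats::poisson()))
               })
    }
    cf <- stats::coef(f)
    sef <- tryCatch(sqrt(diag(stats::vcov(f))), error = function(e) rep(NA_real_, length(cf)))
    alpha[i, ] <- cf[seq_len(K)]
    alpha_se[i, ] <- sef[seq_len(K)]
    bdir[i, nb] <- cf[-seq_len(K)]
    bdir_se[i, nb] <- sef[-seq_len(K)]
    if (!is.null(f$theta)) disp[i] <- f$theta
    total_ll <- total_ll + as.numeric(stats::logLik(f))
    conv <- conv && f$converged
    iters <- max(iters, f$iter %||% 0L)
  }
  beta <- (bdir + t(bdir)) / 2
  diag(beta) <- 0
  beta[!ok, ] <- NA_real_; beta[, !ok] <- NA_real_; diag(beta) <- 0
  if (family == "poisson" && any(beta > 0, na.rm = TRUE)) {
    warning("positive beta under the poisson node model: interpret as a ",
            "conditional association, not a normalizable joint Poisson MRF",
            call. = FALSE)
  }
  beta_fill <- beta; beta_fill[is.na(beta_fill)] <- 0
  params <- mrf_params(ifelse(is.na(alpha), 0, alpha), beta_fill,
                       colnames(Y), colnames(X))
  params$alpha[is.na(alpha)] <- NA_real_
  params$beta[is.na(beta)] <- NA_real_; diag(params$beta) <- 0
  list(params = params, method = family,
       converged = conv, final_objective = total_ll / nrow(Y),
       n_iterations = iters,
       standard_errors = list(alpha = alpha_se,
                              beta = sqrt((bdir_se^2 + t(bdir_se)^2)) / 2),
       penalty = 0, dispersion = disp,
       degenerate_species = character(0), dropped_species = dropped)
}

# ---- methods --------------------------------------------------------------

#' @export
print.mrf_fit <- function(x, ...) {
  cat(sprintf("Markov network fit (%s)\n", x$method))
  cat(sprintf("  %d sites, %d species, %d factors\n",
              nrow(x$data), length(x$params$species_names),
              length(x$params$factor_names)))
  cat(sprintf("  converged: %s after %d iterations; objective %.4f\n",
              x$converged, x$n_iterations, x$final_objective))
  if (length(x$dropped_species)) {
    cat("  dropped species:", paste(x$dropped_species, collapse = ", "), "\n")
  }
  if (length(x$degenerate_species)) {
    cat("  degenerate species:", paste(x$degenerate_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mrf_fit <- function(object, ...) {
  list(alpha = object$params$alpha, beta = object$params$beta)
}

#' @export
logLik.mrf_fit <- function(object, ...) {
  val <- if (object$method == "exact_ml") {
    log_likelihood(object$data, object$covars, object$params)
  } else {
    object$final_objective * nrow(object$data)   # pseudo/conditional objective
  }
  structure(val, df = n_free_params(object$params), class = "logLik")
}

#' @export
summary.mrf_fit <- function(object, ...) {
  p <- object$params
  se <- object$standard_errors
  ut <- which(upper.tri(p$beta), arr.ind = TRUE)
  pairs <- data.frame(
    species_i = p$species_names[ut[, 1]],
    species_j = p$species_names[ut[, 2]],
    beta = p$beta[ut],
    se = if (!is.null(se)) se$beta[ut] else NA_real_)
  pairs$z <- pairs$beta / pairs$se
  al <- expand.grid(species = p$species_names, factor = p$factor_names,
                    stringsAsFactors = FALSE)
  al$alpha <- as.vector(p$alpha)
  al$se <- if (!is.null(se)) as.vector(se$alpha) else NA_real_
  al$z <- al$alpha / al$se
  structure(list(fit = object, alpha_table = al, beta_table = pairs),
            class = "summary.mrf_fit")
}

#' @export
print.summary.mrf_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSpecies-environment effects (alpha):\n")
  print(format(x$alpha_table, digits = 3), row.names = FALSE)
  cat("\nSpecies-species associations (beta):\n")
  print(format(x$beta_table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Simulate community matrices from a fitted Markov network
#'
#' Draws new site-by-species occurrence matrices from the fitted model via
#' the package's Gibbs sampler, using the covariates the model was fitted
#' to (or new ones).
#'
#' @param object an `mrf_fit` from an occurrence-mode method.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param covars covariates to condition on; defaults to the training ones.
#' @param ... passed to [gibbs_sample()].
#' @return a list of `nsim` [community_matrix()] objects.
#' @export
simulate.mrf_fit <- function(object, nsim = 1, seed = NULL, covars = NULL, ...) {
  if (!object$method %in% c("exact_ml", "pseudolikelihood")) {
    stop("simulate() is defined for occurrence-mode fits only", call. = FALSE)
  }
  covars <- covars %||% object$covars
  params <- object$params
  params$alpha[is.na(params$alpha)] <- 0
  params$beta[is.na(params$beta)] <- 0
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nsim))
  lapply(seeds, function(s) gibbs_sample(params, covars, seed = s, ...))
}

#' Node-conditional predictions from a fitted Markov network
#'
#' For occurrence fits, the probability that each species is present at
#' each site given the observed occupancies of all other species and the
#' site's covariates; for count fits, the conditional mean abundance.
#'
#' @param object an `mrf_fit`.
#' @param data,covars data to predict for; default the training data.
#' @param ... unused.
#' @return a sites x species numeric matrix.
#' @export
predict.mrf_fit <- function(object, data = NULL, covars = NULL, ...) {
  data <- data %||% object$data
  covars <- align_covariates(data, covars %||% object$covars)
  p <- object$params
  alpha <- p$alpha; alpha[is.na(alpha)] <- 0
  beta <- p$beta; beta[is.na(beta)] <- 0
  eta <- unclass(covars) %*% t(alpha) + unclass(data) %*% beta
  if (object$method %in% c("exact_ml", "pseudolikelihood")) {
    stats::plogis(eta)
  } else {
    exp(eta)
  }
}

#' @export
residuals.mrf_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- predict(object)
  Y <- unclass(object$data)
  r <- Y - mu
  if (type == "pearson") {
    v <- if (object$method %in% c("exact_ml", "pseudolikelihood")) mu * (1 - mu) else mu
    r <- r / sqrt(pmax(v, 1e-12))
  }
  r
}

#' @export
plot.mrf_fit <- function(x, ...) {
  b <- x$params$beta
  b[is.na(b)] <- 0
  S <- nrow(b)
  graphics::image(seq_len(S), seq_len(S), t(b[S:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "Blue-Red 3", rev = TRUE),
                  zlim = max(abs(b)) * c(-1, 1) + c(-1e-9, 1e-9),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "fitted species-species associations (beta)")
  graphics::axis(1, seq_len(S), x$params$species_names, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(S), rev(x$params$species_names), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Serialize a fit to CSV matrices plus a JSON sidecar
#'
#' Writes `alpha.csv` (species x factors), `beta.csv` (species x species)
#' and `fit.json` (method, convergence, penalty, objective) into `dir`.
#'
#' @param fit an `mrf_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "alpha.csv")
  pb <- file.path(dir, "beta.csv")
  pj <- file.path(dir, "fit.json")
  utils::write.csv(data.frame(species = rownames(fit$params$alpha),
                              fit$params$alpha, check.names = FALSE),
                   pa, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(species = rownames(fit$params$beta),
                              fit$params$beta, check.names = FALSE),
                   pb, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(method = fit$method, converged = fit$converged,
         penalty = fit$penalty, final_objective = fit$final_objective,
         n_iterations = fit$n_iterations,
         dropped_species = fit$dropped_species,
         degenerate_species = fit$degenerate_species),
    pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pa, pb, pj))
}
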
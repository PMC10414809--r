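# Pairwise binary Markov network: p(y | x) proportional to
#   exp( sum_i (alpha_i . x) y_i + sum_{i<j} beta_ij y_i y_j ).
# The pairwise sum runs over unordered pairs i < j (one term per species
# pair, no factor of 2, no self terms), so each fitted beta_ij is the weight
# of the single undirected link between species i and j.

# exact operations enumerate all 2^S configurations; refuse above this
ENUM_LIMIT <- 20L

#' Enumerate all binary configurations of S species
#'
#' Row `k` encodes integer `k - 1` with species 1 as the least-significant
#' bit, giving a deterministic iteration order.
#'
#' @param S species count (must be <= 20).
#' @return a 2^S x S 0/1 matrix.
#' @keywords internal
enum_configs <- function(S) {
  if (S > ENUM_LIMIT) {
    stop("species pool too large for exhaustive enumeration (S = ", S,
         " > ", ENUM_LIMIT, "); use pseudolikelihood", call. = FALSE)
  }
  k <- 0:(2^S - 1)
  m <- vapply(seq_len(S), function(i) (k %/% 2^(i - 1)) %% 2, numeric(length(k)))
  matrix(m, nrow = length(k), ncol = S)
}

check_y_x <- function(y, x, params) {
  if (length(y) != n_species(params)) stop_dims("y", length(y), n_species(params))
  if (length(x) != n_factors(params)) stop_dims("x", length(x), n_factors(params))
}

#' Unnormalized log-probability of a species configuration
#'
#' Evaluates the exponent of the Markov network at one site:
#' `sum_i (alpha_i . x) y_i + sum_{i<j} beta_ij y_i y_j`.
#'
#' @param y 0/1 occupancy vector (length = species count).
#' @param x covariate vector (length = factor count).
#' @param params an [mrf_params()] object.
#' @return scalar log-potential.
#' @examples
#' p <- mrf_params(matrix(c(0.2, -0.1), 2, 1), matrix(c(0, .3, .3, 0), 2, 2))
#' log_potential(c(1, 1), 1, p)   # 0.2 - 0.1 + 0.3 = 0.4
#' @export
log_potential <- function(y, x, params) {
  check_y_x(y, x, params)
  lin <- drop(params$alpha %*% x)
  sum(lin * y) + 0.5 * drop(y %*% params$beta %*% y)
}

#' Log partition function of the Markov network at one site
#'
#' `log` of the sum of `exp(log_potential)` over all 2^S configurations.
#' Site-specific because alpha acts through the covariates `x`.
#'
#' @inheritParams log_potential
#' @return scalar log normalizing constant.
#' @export
log_partition <- function(x, params) {
  if (length(x) != n_factors(params)) stop_dims("x", length(x), n_factors(params))
  logsumexp(config_log_potentials(x, params))
}

# log-potential of every configuration at covariates x, in enum_configs order
config_log_potentials <- function(x, params) {
  C <- enum_configs(n_species(params))
  lin <- drop(params$alpha %*% x)
  drop(C %*% lin) + 0.5 * rowSums((C %*% params$beta) * C)
}

#' Exact configuration distribution at one site
#'
#' Enumerates all 2^S occupancy configurations and their normalized
#' probabilities under the model; mostly a test oracle and a moment-matching
#' device for the exact fitter.
#'
#' @inheritParams log_potential
#' @return a data.frame with one 0/1 column per species plus `probability`
#'   (sums to 1), rows in binary-counting order (species 1 = least
#'   significant bit).
#' @export
configuration_probabilities <- function(x, params) {
  lp <- config_log_potentials(x, params)
  pr <- exp(lp - logsumexp(lp))
  C <- enum_configs(n_species(params))
  colnames(C) <- params$species_names
  out <- as.data.frame(C)
  out$probability <- pr
  out
}

#' Exact log-likelihood of occurrence data under a Markov network
#'
#' Sum over sites of `log_potential - log_partition`; always <= 0. Sites
#' sharing identical covariate rows share one partition-function
#' evaluation.
#'
#' @param data occurrence-mode [community_matrix()].
#' @param covars [covariate_matrix()] aligned by site id, or `NULL` for an
#'   intercept-only design.
#' @param params an [mrf_params()] object.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, covars, params) {
  if (community_mode(data) != "occurrence") {
    stop("log_likelihood is defined for occurrence data; ",
         "fit abundance data with mrf_fit(method = 'poisson'/'negbin')",
         call. = FALSE)
  }
  covars <- align_covariates(data, covars)
  if (ncol(data) != n_species(params)) stop_dims("data species", ncol(data), n_species(params))
  if (ncol(covars) != n_factors(params)) stop_dims("covars factors", ncol(covars), n_factors(params))
  Y <- unclass(data)
  X <- unclass(covars)
  lin <- X %*% t(params$alpha)                      # sites x species
  pot <- rowSums(lin * Y) + 0.5 * rowSums((Y %*% params$beta) * Y)
  key <- apply(X, 1, paste, collapse = "\r")
  groups <- split(seq_len(nrow(X)), key)
  logZ <- numeric(nrow(X))
  for (g in groups) logZ[g] <- log_partition(X[g[1], ], params)
  sum(pot) - sum(logZ)
}

# ---- sufficient-statistic machinery (shared by exact fitter) -------------

# theta packing: c(vec(alpha), beta[upper.tri]) with upper.tri in R's
# column-major order.
pack_params <- function(params) {
  c(as.vector(params$alpha), params$beta[upper.tri(params$beta)])
}

unpack_params <- function(theta, S, K, species_names, factor_names) {
  alpha <- matrix(theta[seq_len(S * K)], S, K)
  beta <- matrix(0, S, S)
  beta[upper.tri(beta)] <- theta[-seq_len(S * K)]
  beta <- beta + t(beta)
  mrf_params(alpha, beta, species_names, factor_names)
}

# feature matrix of all configurations at covariates x:
# columns ordered as pack_params (alpha features y_i * x_k, then pair
# features y_i y_j for i < j)
config_features <- function(C, x) {
  S <- ncol(C)
  af <- do.call(cbind, lapply(seq_along(x), function(k) C * x[k]))
  ut <- which(upper.tri(diag(S)), arr.ind = TRUE)
  pf <- C[, ut[, 1], drop = FALSE] * C[, ut[, 2], drop = FALSE]
  cbind(af, pf)
}

# observed per-site-mean sufficient statistics of a dataset
observed_stats <- function(Y, X) {
  S <- ncol(Y)
  af <- as.vector(crossprod(Y, X))                  # sum_s y_si x_sk, vec over (i,k)
  cooc <- crossprod(Y)
  c(af, cooc[upper.tri(cooc)]) / nrow(Y)
}
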
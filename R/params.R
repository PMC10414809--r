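#' Markov network parameters
#'
#' Container for the model's weights: `alpha` holds the direct effect of
#' each environmental factor (or microhabitat indicator) on each species,
#' and `beta` the symmetric pairwise association between species.
#' `beta` must be exactly symmetric with zero diagonal -- species pairs
#' carry a single undirected association, and intraspecific terms are not
#' part of the occurrence model (self-regulation enters only at the
#' dynamics level, see [rescale_from_mrf()]).
#'
#' @param alpha species x factors numeric matrix.
#' @param beta species x species numeric matrix, symmetric, zero diagonal.
#' @param species_names,factor_names label vectors; default from dimnames.
#' @return an object of class `mrf_params` (a list with elements `alpha`,
#'   `beta`, `species_names`, `factor_names`).
#' @examples
#' p <- mrf_params(alpha = matrix(c(0.2, -0.1), 2, 1),
#'                 beta = matrix(c(0, 0.3, 0.3, 0), 2, 2))
#' p$beta
#' @export
mrf_params <- function(alpha, beta, species_names = NULL, factor_names = NULL) {
  alpha <- as.matrix(alpha)
  beta <- as.matrix(beta)
  S <- nrow(alpha)
  if (!all(dim(beta) == c(S, S))) stop_dims("beta", dim(beta), c(S, S))
  if (!isTRUE(all.equal(beta, t(beta), tolerance = 0, check.attributes = FALSE))) {
    stop("beta must be exactly symmetric", call. = FALSE)
  }
  if (any(diag(beta) != 0)) stop("beta must have a zero diagonal", call. = FALSE)
  species_names <- as.character(species_names %||% rownames(alpha) %||%
                                  paste0("sp_", seq_len(S)))
  factor_names <- as.character(factor_names %||% colnames(alpha) %||%
                                 paste0("f_", seq_len(ncol(alpha))))
  if (length(species_names) != S) stop_dims("species_names", length(species_names), S)
  if (length(factor_names) != ncol(alpha)) {
    stop_dims("factor_names", length(factor_names), ncol(alpha))
  }
  dimnames(alpha) <- list(species_names, factor_names)
  dimnames(beta) <- list(species_names, species_names)
  structure(list(alpha = alpha, beta = beta, species_names = species_names,
                 factor_names = factor_names),
            class = "mrf_params")
}

#' @export
print.mrf_params <- function(x, ...) {
  cat(sprintf("mrf_params: %d species, %d environmental factors\n",
              length(x$species_names), length(x$factor_names)))
  cat("alpha (species x factors):\n"); print(round(x$alpha, 4))
  cat("beta (upper triangle):\n")
  ut <- which(upper.tri(x$beta), arr.ind = TRUE)
  if (nrow(ut)) {
    df <- data.frame(pair = paste(x$species_names[ut[, 1]], x$species_names[ut[, 2]],
                                  sep = "--"),
                     beta = round(x$beta[ut], 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

n_species <- function(params) length(params$species_names)
n_factors <- function(params) length(params$factor_names)

#' Number of free parameters (alpha entries + unordered species pairs)
#' @param params an `mrf_params` object.
#' @keywords internal
n_free_params <- function(params) {
  S <- n_species(params)
  S * n_factors(params) + S * (S - 1L) / 2L
}
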
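#' Site-by-species community matrix
#'
#' The basic data container: a sites x species matrix of occurrences (0/1)
#' or non-negative integer abundances, with unique site identifiers and
#' species names. A row is the observed species pool of one site; in
#' occurrence mode row `s` is the binary configuration vector of that site.
#'
#' @param values numeric matrix (sites x species) of non-negative integers;
#'   all entries must be 0/1 when `mode = "occurrence"`.
#' @param site_ids character vector of unique site identifiers; defaults to
#'   rownames or `site_1 ... site_n`.
#' @param species_names character vector of unique species names; defaults to
#'   colnames or `sp_1 ... sp_S`.
#' @param mode `"occurrence"`, `"abundance"`, or `"auto"` (occurrence iff all
#'   entries are 0 or 1).
#' @return an object of class `community_matrix`: the integer matrix with
#'   dimnames set and attributes `mode`.
#' @examples
#' m <- community_matrix(rbind(c(1, 0), c(1, 1)),
#'                       species_names = c("sub1", "sub2"))
#' attr(m, "mode")
#' @export
community_matrix <- function(values, site_ids = NULL, species_names = NULL,
                             mode = c("auto", "occurrence", "abundance")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("community matrix has non-finite entries", call. = FALSE)
  if (any(values < 0)) stop("community matrix has negative entries", call. = FALSE)
  if (any(values != round(values))) stop("community matrix has non-integer entries", call. = FALSE)
  site_ids <- as.character(site_ids %||% rownames(values) %||%
                             paste0("site_", seq_len(nrow(values))))
  species_names <- as.character(species_names %||% colnames(values) %||%
                                  paste0("sp_", seq_len(ncol(values))))
  if (length(site_ids) != nrow(values)) stop_dims("site_ids", length(site_ids), nrow(values))
  if (length(species_names) != ncol(values)) stop_dims("species_names", length(species_names), ncol(values))
  if (anyDuplicated(site_ids)) {
    stop("duplicate site_id: ", site_ids[duplicated(site_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(species_names)) {
    stop("duplicate species name: ", species_names[duplicated(species_names)][1], call. = FALSE)
  }
  if (mode == "auto") mode <- if (all(values %in% c(0, 1))) "occurrence" else "abundance"
  if (mode == "occurrence" && !all(values %in% c(0, 1))) {
    stop("mode = 'occurrence' but matrix has entries other than 0/1", call. = FALSE)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(site_ids, species_names)
  structure(values, mode_flag = mode, class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species (%s mode)\n",
              nrow(x), ncol(x), attr(x, "mode_flag")))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more sites)\n", sep = "")
  invisible(x)
}

#' Mode flag of a community matrix
#' @param x a `community_matrix`.
#' @return `"occurrence"` or `"abundance"`.
#' @export
community_mode <- function(x) attr(x, "mode_flag")

#' Site-by-factor covariate matrix
#'
#' Environmental covariates per site. Categorical microhabitat labels are
#' one-hot expanded with [one_hot_microhabitat()]; an intercept, if wanted,
#' is an explicit all-ones column supplied by the caller.
#'
#' @param values numeric matrix (sites x factors).
#' @param site_ids,factor_names identifiers as in [community_matrix()].
#' @return an object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, site_ids = NULL, factor_names = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("covariate matrix has non-finite entries", call. = FALSE)
  site_ids <- as.character(site_ids %||% rownames(values) %||%
                             paste0("site_", seq_len(nrow(values))))
  factor_names <- as.character(factor_names %||% colnames(values) %||%
                                 paste0("f_", seq_len(ncol(values))))
  if (length(site_ids) != nrow(values)) stop_dims("site_ids", length(site_ids), nrow(values))
  if (length(factor_names) != ncol(values)) stop_dims("factor_names", length(factor_names), ncol(values))
  if (anyDuplicated(site_ids)) stop("duplicate site_id in covariates", call. = FALSE)
  if (anyDuplicated(factor_names)) stop("duplicate factor name", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(site_ids, factor_names)
  structure(values, class = c("covariate_matrix", "matrix", "array"))
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("covariate_matrix: %d sites x %d factors\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

#' One-hot expansion of a categorical microhabitat label
#'
#' Expands a per-site label vector (e.g. nurse vs open microhabitat) into
#' one-hot indicator columns that sum to 1 per site, named
#' `<prefix><level>`.
#'
#' @param labels character or factor vector, one label per site.
#' @param site_ids optional site identifiers.
#' @param prefix prepended to each level to form factor names.
#' @return a `covariate_matrix` of 0/1 indicators.
#' @export
one_hot_microhabitat <- function(labels, site_ids = NULL, prefix = "") {
  labels <- as.factor(labels)
  m <- stats::model.matrix(~ labels - 1)
  colnames(m) <- paste0(prefix, levels(labels))
  covariate_matrix(m, site_ids = site_ids, factor_names = colnames(m))
}

#' Align a covariate matrix to a community matrix by site identifier
#' @param data a `community_matrix`.
#' @param covars a `covariate_matrix`, or `NULL` for an intercept-only design.
#' @return a `covariate_matrix` whose rows match `data` one-for-one.
#' @keywords internal
align_covariates <- function(data, covars) {
  if (is.null(covars)) {
    return(covariate_matrix(matrix(1, nrow(data), 1), site_ids = rownames(data),
                            factor_names = "intercept"))
  }
  missing <- setdiff(rownames(data), rownames(covars))
  if (length(missing)) {
    stop("covariate matrix is missing sites: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  covariate_matrix(unclass(covars)[rownames(data), , drop = FALSE],
                   site_ids = rownames(data), factor_names = colnames(covars))
}

# ---- CSV round trip -------------------------------------------------------
# Fixed dialect: comma, UTF-8, "." decimal, first column "site_id".

#' Read / write community and covariate matrices as CSV
#'
#' Files have a header row, a leading `site_id` column, and one column per
#' species (or environmental factor). The occurrence/abundance mode of a
#' community matrix is auto-detected (all entries in \{0,1\} means
#' occurrence) unless overridden.
#'
#' @param path file path.
#' @param mode mode override passed to [community_matrix()].
#' @return the parsed `community_matrix` / `covariate_matrix`.
#' @export
read_community_csv <- function(path, mode = c("auto", "occurrence", "abundance")) {
  df <- read_matrix_csv(path)
  community_matrix(df$values, site_ids = df$site_ids, species_names = df$names,
                   mode = match.arg(mode))
}

#' @rdname read_community_csv
#' @export
read_covariate_csv <- function(path) {
  df <- read_matrix_csv(path)
  covariate_matrix(df$values, site_ids = df$site_ids, factor_names = df$names)
}

read_matrix_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr)) {
    stop("duplicate species/factor column '", hdr[duplicated(hdr)][1],
         "' in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L || names(df)[1] != "site_id") {
    stop("expected a 'site_id' first column in ", path, call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric column '", names(vals)[bad[1]], "' in ", path, call. = FALSE)
  }
  list(values = as.matrix(vals), site_ids = as.character(df$site_id), names = names(vals))
}

#' @param x the matrix object to write.
#' @rdname read_community_csv
#' @export
write_community_csv <- function(x, path) write_matrix_csv(x, path)

#' @rdname read_community_csv
#' @export
write_covariate_csv <- function(x, path) write_matrix_csv(x, path)

write_matrix_csv <- function(x, path) {
  df <- data.frame(site_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
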
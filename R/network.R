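#' Assemble a two-layer constructive network
#'
#' Collates the species--environment effects (`alpha`) and the
#' species--species associations (`beta`) of a Markov network into a single
#' two-layer signed network: environment/microhabitat nodes link to species
#' through the alpha layer, species link to each other through the beta
#' layer. A positive alpha marks association with a microhabitat or
#' environmental factor, a negative alpha avoidance; likewise beta > 0 for
#' positively and beta < 0 for negatively associated species pairs. Each
#' unordered species pair carries at most one link, stored with canonical
#' `species_i < species_j` ordering; zero-weight links are never stored.
#'
#' A link enters the network when it passes *every* filter supplied:
#' significance under the corresponding permutation screen (q below `fdr`),
#' directional coherence, and magnitude at least `min_weight`. With no
#' screen, only the magnitude filter applies.
#'
#' Directional coherence: a fixed-margin ensemble is negatively biased
#' (fixed site richness makes species compete for slots), so a pair can be
#' "significant" because its estimate lies *above* a negative null mean
#' while its raw weight is slightly negative. Labelling that link a
#' negative association would contradict the direction of the evidence;
#' screened links are therefore kept only when `sign(weight)` equals the
#' sign of the permutation z-score.
#'
#' @param params an [mrf_params()] or [mrf_fit()] object.
#' @param screen optional beta-layer [screen_beta()] result.
#' @param alpha_screen optional alpha-layer [screen_alpha()] result.
#' @param fdr q-value threshold applied to the screens.
#' @param min_weight minimum absolute parameter value for a link.
#' @param provenance free-form list recorded in the object.
#' @return an object of class `constructive_network`: lists of species and
#'   environment nodes, an `alpha_links` data.frame (`species`, `factor`,
#'   `weight`, `sign`, `q`), a `beta_links` data.frame (`species_i`,
#'   `species_j`, `weight`, `sign`, `q`), and provenance.
#' @examples
#' p <- mrf_params(matrix(c(1, -1), 2, 1), matrix(c(0, .8, .8, 0), 2, 2))
#' net <- build_network(p, min_weight = 0.5)
#' net$beta_links
#' @export
build_network <- function(params, screen = NULL, alpha_screen = NULL,
                          fdr = 0.05, min_weight = 0, provenance = list()) {
  if (inherits(params, "mrf_fit")) {
    provenance <- utils::modifyList(list(fit_method = params$method,
                                         penalty = params$penalty), provenance)
    params <- params$params
  }
  stopifnot(inherits(params, "mrf_params"))
  check_screen_labels <- function(sc, rows, cols) {
    if (!identical(rownames(sc$observed), rows) ||
        !identical(colnames(sc$observed), cols)) {
      stop("screen labels do not match the parameter labels", call. = FALSE)
    }
  }
  sp <- params$species_names
  fa <- params$factor_names

  ut <- which(upper.tri(params$beta), arr.ind = TRUE)
  bw <- params$beta[ut]
  bq <- rep(NA_real_, length(bw))
  keep <- !is.na(bw) & bw != 0 & abs(bw) >= min_weight
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "mrf_screen"), screen$layer == "beta")
    check_screen_labels(screen, sp, sp)
    bq <- screen$q_values[ut]
    keep <- keep & !is.na(bq) & bq < fdr & sign(screen$z_scores[ut]) == sign(bw)
  }
  beta_links <- data.frame(species_i = sp[ut[, 1]], species_j = sp[ut[, 2]],
                           weight = bw, sign = sign(bw), q = bq,
                           stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # canonical i < j ordering by species name for deterministic serialization
  flip <- beta_links$species_i > beta_links$species_j
  tmp <- beta_links$species_i[flip]
  beta_links$species_i[flip] <- beta_links$species_j[flip]
  beta_links$species_j[flip] <- tmp
  beta_links <- beta_links[order(beta_links$species_i, beta_links$species_j), ,
                           drop = FALSE]
  rownames(beta_links) <- NULL

  aw <- as.vector(params$alpha)
  grid <- expand.grid(species = sp, factor = fa, stringsAsFactors = FALSE)
  aq <- rep(NA_real_, length(aw))
  akeep <- !is.na(aw) & aw != 0 & abs(aw) >= min_weight
  if (!is.null(alpha_screen)) {
    stopifnot(inherits(alpha_screen, "mrf_screen"), alpha_screen$layer == "alpha")
    check_screen_labels(alpha_screen, sp, fa)
    aq <- as.vector(alpha_screen$q_values)
    akeep <- akeep & !is.na(aq) & aq < fdr &
      sign(as.vector(alpha_screen$z_scores)) == sign(aw)
  }
  alpha_links <- data.frame(species = grid$species, factor = grid$factor,
                            weight = aw, sign = sign(aw), q = aq,
                            stringsAsFactors = FALSE)[akeep, , drop = FALSE]
  alpha_links <- alpha_links[order(alpha_links$factor, alpha_links$species), ,
                             drop = FALSE]
  rownames(alpha_links) <- NULL

  structure(list(species_nodes = sp, environment_nodes = fa,
                 alpha_links = alpha_links, beta_links = beta_links,
                 provenance = utils::modifyList(
                   list(fdr = if (is.null(screen) && is.null(alpha_screen)) NA_real_ else fdr,
                        min_weight = min_weight,
                        screened_beta = !is.null(screen),
                        screened_alpha = !is.null(alpha_screen)),
                   provenance)),
            class = "constructive_network")
}

#' @export
print.constructive_network <- function(x, ...) {
  cat("constructive network\n")
  cat(sprintf("  nodes: %d species, %d environment factors\n",
              length(x$species_nodes), length(x$environment_nodes)))
  cat(sprintf("  alpha layer: %d links (%d positive, %d negative)\n",
              nrow(x$alpha_links), sum(x$alpha_links$sign > 0),
              sum(x$alpha_links$sign < 0)))
  cat(sprintf("  beta layer:  %d links (%d positive, %d negative)\n",
              nrow(x$beta_links), sum(x$beta_links$sign > 0),
              sum(x$beta_links$sign < 0)))
  invisible(x)
}

#' Layer-wise summary of a constructive network
#'
#' @param net a `constructive_network`.
#' @return a list with per-layer positive/negative link counts, connectance
#'   (realized / possible links: `S * K` for the alpha layer,
#'   `S (S - 1) / 2` for the beta layer), fraction of positive links, and
#'   per-species degree (links in either layer).
#' @export
network_summary <- function(net) {
  S <- length(net$species_nodes)
  K <- length(net$environment_nodes)
  a <- net$alpha_links; b <- net$beta_links
  degree <- stats::setNames(rep(0L, S), net$species_nodes)
  for (s in a$species) degree[s] <- degree[s] + 1L
  for (s in c(b$species_i, b$species_j)) degree[s] <- degree[s] + 1L
  frac_pos <- function(df) if (nrow(df)) mean(df$sign > 0) else NA_real_
  list(
    alpha = list(n_links = nrow(a), n_positive = sum(a$sign > 0),
                 n_negative = sum(a$sign < 0),
                 connectance = if (S * K) nrow(a) / (S * K) else 0,
                 fraction_positive = frac_pos(a)),
    beta = list(n_links = nrow(b), n_positive = sum(b$sign > 0),
                n_negative = sum(b$sign < 0),
                connectance = if (S > 1) nrow(b) / (S * (S - 1) / 2) else 0,
                fraction_positive = frac_pos(b)),
    degree = degree)
}

#' Convert a constructive network to an igraph object
#'
#' Nodes carry a `type` attribute (`"species"` / `"environment"`); edges a
#' `layer` (`"alpha"` / `"beta"`), `weight`, `sign` and `q_value`. Alpha
#' edges are directed environment factor to species (the microhabitat acts
#' on the plant); beta edges are undirected associations stored with
#' canonical orientation.
#'
#' @param net a `constructive_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  nodes <- data.frame(
    name = c(net$species_nodes, net$environment_nodes),
    type = rep(c("species", "environment"),
               c(length(net$species_nodes), length(net$environment_nodes))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(net$alpha_links)) data.frame(
      from = net$alpha_links$factor, to = net$alpha_links$species,
      layer = "alpha", weight = net$alpha_links$weight,
      sign = net$alpha_links$sign, q_value = net$alpha_links$q,
      stringsAsFactors = FALSE),
    if (nrow(net$beta_links)) data.frame(
      from = net$beta_links$species_i, to = net$beta_links$species_j,
      layer = "beta", weight = net$beta_links$weight,
      sign = net$beta_links$sign, q_value = net$beta_links$q,
      stringsAsFactors = FALSE))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), layer = character(),
                        weight = numeric(), sign = numeric(), q_value = numeric())
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Export a constructive network
#'
#' `write_network_graphml()` writes GraphML via igraph; `write_edge_tsv()`
#' writes a deterministic TSV edge list (`source`, `target`, `layer`,
#' `weight`, `q_value`) that `read_edge_tsv()` parses back losslessly.
#'
#' @param net a `constructive_network`.
#' @param path output file.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_tsv <- function(net, path) {
  g <- as_igraph(net)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.table(el[, c("source", "target", "layer", "weight", "q_value")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_edge_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @export
plot.constructive_network <- function(x, ...) {
  g <- as_igraph(x)
  if (igraph::ecount(g) == 0 && igraph::vcount(g) == 0) {
    stop("empty network", call. = FALSE)
  }
  vt <- igraph::V(g)$type
  cols <- ifelse(vt == "environment", "khaki", "lightsteelblue")
  shapes <- ifelse(vt == "environment", "square", "circle")
  ec <- if (igraph::ecount(g)) ifelse(igraph::E(g)$sign > 0, "steelblue4", "firebrick")
        else character(0)
  ew <- if (igraph::ecount(g)) 1 + 3 * abs(igraph::E(g)$weight) /
          max(abs(igraph::E(g)$weight)) else numeric(0)
  # signed weights would confuse force-directed layout; place nodes unweighted
  lay <- igraph::layout_with_fr(g, weights = NA)
  igraph::plot.igraph(g, layout = lay, vertex.color = cols,
                      vertex.shape = shapes, edge.color = ec, edge.width = ew,
                      edge.arrow.size = 0.4, ...)
  invisible(x)
}
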
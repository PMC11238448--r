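#' k-nearest-neighbour population network
#'
#' Builds an undirected simple graph on a genetic distance matrix: each
#' individual is connected to its k smallest-distance neighbours, with
#' deterministic tie-breaking by (distance, id).  Under the default
#' union rule an edge is kept if either endpoint selects it (NetView's
#' default, minimum degree k); the mutual rule keeps only reciprocal
#' selections.
#'
#' @param D Symmetric distance matrix with zero diagonal and ids as
#'   dimnames.
#' @param k Number of neighbours (default 10; must be < n).
#' @param rule "union" (default) or "mutual".
#' @return An [igraph::graph] with vertex attribute `population` unset
#'   and edge attributes `weight` and `distance` (equal).
#' @export
knn_network <- function(D, k = 10, rule = c("union", "mutual")) {
  rule <- match.arg(rule)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of individuals")
  ids <- rownames(D) %||% as.character(seq_len(n))
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    ord <- order(d, ids)
    ord <- ord[ord != i]
    sel[i, ord[seq_len(k)]] <- TRUE
  }
  adj <- if (rule == "union") sel | t(sel) else sel & t(sel)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = D[idx], distance = D[idx],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g
}

#' Annotate a population network with per-individual statistics
#'
#' Joins contribution scores, ROH summaries, admixture proportions and
#' population labels onto the vertices by id.  Each admixture component
#' becomes a numeric attribute `q_<cluster>`, so the attributes survive
#' GraphML export.
#'
#' @param network Graph from [knn_network()].
#' @param scores Optional data frame `id`, `score` (and `rank`) from
#'   [contribution_scores()].
#' @param roh_summary Optional per-individual data frame with `id` and
#'   `f_roh` columns (see [summarize_roh()]).
#' @param admixture Optional `admix_fit` or Q matrix with ids as
#'   rownames.
#' @param populations Optional named character vector of labels.
#' @return The annotated graph.
#' @export
annotate_network <- function(network, scores = NULL, roh_summary = NULL,
                             admixture = NULL, populations = NULL) {
  ids <- igraph::V(network)$name
  need <- function(have, what) {
    missing_ids <- setdiff(ids, have)
    if (length(missing_ids)) {
      stop(what, " lacks id(s): ", paste(missing_ids, collapse = ", "))
    }
  }
  if (!is.null(scores)) {
    need(scores$id, "scores")
    i <- match(ids, scores$id)
    network <- igraph::set_vertex_attr(network, "gc", value = scores$score[i])
    if ("rank" %in% names(scores)) {
      network <- igraph::set_vertex_attr(network, "gc_rank", value = scores$rank[i])
    }
  }
  if (!is.null(roh_summary)) {
    need(roh_summary$id, "roh_summary")
    i <- match(ids, roh_summary$id)
    network <- igraph::set_vertex_attr(network, "f_roh",
                                       value = roh_summary$f_roh[i])
  }
  if (!is.null(admixture)) {
    Q <- if (inherits(admixture, "admix_fit")) admixture$Q else as.matrix(admixture)
    need(rownames(Q), "admixture")
    i <- match(ids, rownames(Q))
    for (k in seq_len(ncol(Q))) {
      network <- igraph::set_vertex_attr(
        network, paste0("q_", colnames(Q)[k] %||% k), value = Q[i, k])
    }
  }
  if (!is.null(populations)) {
    need(names(populations), "populations")
    network <- igraph::set_vertex_attr(network, "population",
                                       value = unname(populations[ids]))
  }
  network
}

#' Edge rendering table with distance-based thickness
#'
#' Maps each edge's genetic distance to a thickness in `[0, 1]` by
#' min-max normalising (1 - distance), so the smallest distance gets
#' maximal thickness and the ordering of thickness is the reverse of
#' the distance ordering.  If all distances are equal every edge gets
#' thickness 1.
#'
#' @param network Graph from [knn_network()].
#' @return Data frame `from`, `to`, `distance`, `thickness`.
#' @export
edge_weight_style <- function(network) {
  el <- igraph::as_data_frame(network, what = "edges")
  d <- el$distance
  rng <- range(d)
  thickness <- if (diff(rng) == 0) rep(1, length(d)) else
    ((1 - d) - (1 - rng[2])) / (rng[2] - rng[1])
  data.frame(from = el$from, to = el$to, distance = d,
             thickness = thickness, stringsAsFactors = FALSE)
}

#' Write a network as GraphML
#'
#' @param network An igraph graph.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
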
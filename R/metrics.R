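# Measure suite on the static network: degree/strength split by direction,
# shortest-path betweenness, eigenvector centrality, density, assortativity,
# and focal-group-to-target connection summaries.

#' Directed degree and strength per node
#'
#' Degree counts discrete exchange events (multigraph semantics): receptions
#' are incoming events, donations outgoing events. Strength sums exchange
#' durations the same way. `count = "partners"` switches degree to distinct
#' partners (simple-graph semantics) instead of events.
#'
#' @param net A `colony_network`.
#' @param count `"events"` (default) or `"partners"` for the degree columns.
#' @return Data frame keyed by `id` with `exchanges_total`, `receptions`,
#'   `donations`, `time_total`, `time_as_receiver`, `time_as_donor`.
#' @export
degree_strength <- function(net, count = c("events", "partners")) {
  count <- match.arg(count)
  ids <- net$nodes$id
  e <- net$edges
  n <- if (count == "events") e$n_events else rep(1L, nrow(e))
  don <- .sum_by(n, e$donor, ids)
  rec <- .sum_by(n, e$receiver, ids)
  td <- .sum_by(e$total_duration, e$donor, ids)
  tr <- .sum_by(e$total_duration, e$receiver, ids)
  data.frame(id = ids,
             exchanges_total = don + rec,
             receptions = rec,
             donations = don,
             time_total = td + tr,
             time_as_receiver = tr,
             time_as_donor = td,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shortest-path betweenness centrality
#'
#' Directed betweenness: the number of shortest paths between every ordered
#' pair of other nodes that pass through the node. Unweighted by default;
#' with `use_weights = TRUE` edge length is `1/total_duration`, so longer
#' (stronger) exchanges give shorter distances.
#'
#' @param net A `colony_network`.
#' @param use_weights Use inverse total duration as edge length?
#' @return Named numeric vector over node ids.
#' @export
betweenness_centrality <- function(net, use_weights = FALSE) {
  g <- as_igraph(net)
  w <- if (use_weights) 1 / igraph::E(g)$total_duration else NA
  b <- igraph::betweenness(g, directed = TRUE, weights = w)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Eigenvector centrality
#'
#' Principal-eigenvector scores of the (by default symmetrized,
#' duration-weighted) adjacency matrix, scaled so the maximum score is 1.
#' The default treats exchanges as undirected ties weighted by total contact
#' time, which keeps scores meaningful on sparse directed graphs whose
#' strongly connected core is tiny; a directed variant is available.
#'
#' @param net A `colony_network` with at least one edge.
#' @param treat_as_undirected Symmetrize the adjacency first? Default `TRUE`.
#' @param use_weights Weight by total exchange duration? Default `TRUE`.
#' @return Named numeric vector over node ids, maximum 1.
#' @export
eigenvector_centrality <- function(net, treat_as_undirected = TRUE,
                                   use_weights = TRUE) {
  if (nrow(net$edges) == 0)
    stop("eigenvector centrality needs at least one edge", call. = FALSE)
  g <- as_igraph(net, undirected = treat_as_undirected)
  w <- if (use_weights) igraph::E(g)$total_duration else NA
  res <- igraph::eigen_centrality(g, directed = !treat_as_undirected, weights = w)
  setNames(as.numeric(res$vector), igraph::V(g)$name)
}

#' Directed edge density
#'
#' Distinct ordered pairs with at least one exchange divided by the
#' theoretical maximum `N (N - 1)`.
#'
#' @param net A `colony_network` with at least two nodes.
#' @return Density in `(0, 1]`.
#' @export
edge_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("edge density is undefined for fewer than 2 nodes", call. = FALSE)
  nrow(net$edges) / (n * (n - 1))
}

#' Nominal (categorical) assortativity
#'
#' Newman's assortativity coefficient on the edge mixing matrix:
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)`, where `e_ij` is
#' the fraction of directed edges from category i to category j and `a`, `b`
#' are its row/column margins. `r = 1` means all edges join like with like;
#' negative values mean disassortative mixing. Edges are counted once per
#' distinct ordered pair by default; `weighted = TRUE` weights each pair by
#' its event count.
#'
#' @param net A `colony_network`.
#' @param labels Node categories: a node column name, named vector, or vector
#'   aligned with `net$nodes`. Defaults to hygienic status. `NA` labels drop
#'   the incident edges.
#' @param weighted Weight pairs by `n_events`?
#' @return Assortativity coefficient in `[-1, 1]`.
#' @export
assortativity_nominal <- function(net, labels = NULL, weighted = FALSE) {
  if (is.null(labels))
    labels <- ifelse(net$nodes$hygienic, "hygienic", "non_hygienic")
  lab <- .node_values(net, labels)
  ld <- lab[match(net$edges$donor, net$nodes$id)]
  lr <- lab[match(net$edges$receiver, net$nodes$id)]
  keep <- !is.na(ld) & !is.na(lr)
  if (!any(keep)) stop("no edges with labeled endpoints", call. = FALSE)
  cats <- sort(unique(c(ld[keep], lr[keep])))
  if (length(cats) < 2)
    stop("nominal assortativity is undefined with a single category", call. = FALSE)
  w <- if (weighted) net$edges$n_events[keep] else rep(1, sum(keep))
  tab <- xtabs(w ~ factor(ld[keep], cats) + factor(lr[keep], cats))
  e <- tab / sum(tab)
  a <- rowSums(e)
  b <- colSums(e)
  sab <- sum(a * b)
  if (1 - sab == 0)
    stop("nominal assortativity is undefined: degenerate mixing matrix", call. = FALSE)
  as.numeric((sum(diag(e)) - sab) / (1 - sab))
}

#' Numeric assortativity
#'
#' Pearson correlation of (donor value, receiver value) over directed edges;
#' used for age assortment. Nodes with unknown values (e.g. unknown age)
#' are excluded together with their incident edges; the number of excluded
#' edges is attached as an attribute.
#'
#' @param net A `colony_network`.
#' @param values Per-node numeric values (column name, named vector, or
#'   vector aligned with `net$nodes`). Defaults to `age_days`.
#' @param weighted Weight edges by `n_events` (weighted correlation)?
#' @return Correlation in `[-1, 1]` with attributes `n_edges` and
#'   `n_edges_excluded`.
#' @export
assortativity_numeric <- function(net, values = "age_days", weighted = FALSE) {
  v <- .node_values(net, values)
  vd <- v[match(net$edges$donor, net$nodes$id)]
  vr <- v[match(net$edges$receiver, net$nodes$id)]
  keep <- !is.na(vd) & !is.na(vr)
  if (sum(keep) < 2)
    stop("numeric assortativity needs at least 2 edges with known values",
         call. = FALSE)
  vd <- vd[keep]; vr <- vr[keep]
  if (sd(vd) == 0 || sd(vr) == 0)
    stop("numeric assortativity is undefined: zero variance in endpoint values",
         call. = FALSE)
  r <- if (weighted) {
    cov.wt(cbind(vd, vr), wt = net$edges$n_events[keep], cor = TRUE)$cor[1, 2]
  } else {
    cor(vd, vr)
  }
  structure(as.numeric(r), n_edges = sum(keep), n_edges_excluded = sum(!keep))
}

#' Per-node connections to a target set
#'
#' For each non-target node, the number of exchanges and the exchange time
#' shared with any node of the target set, split by direction relative to the
#' focal node. This is the per-individual response used for the
#' queen-and-young-workers comparison.
#'
#' @param net A `colony_network`.
#' @param targets Character vector of target node ids.
#' @return Data frame keyed by `id` (non-target nodes only) with `exchanges`,
#'   `as_receiver`, `as_donor`, `time_total`, `time_as_receiver`,
#'   `time_as_donor`.
#' @export
connection_to_targets <- function(net, targets) {
  ids <- setdiff(net$nodes$id, targets)
  e <- net$edges
  to_t <- e$donor %in% ids & e$receiver %in% targets      # focal donated
  from_t <- e$receiver %in% ids & e$donor %in% targets    # focal received
  don <- .sum_by(e$n_events[to_t], e$donor[to_t], ids)
  rec <- .sum_by(e$n_events[from_t], e$receiver[from_t], ids)
  td <- .sum_by(e$total_duration[to_t], e$donor[to_t], ids)
  tr <- .sum_by(e$total_duration[from_t], e$receiver[from_t], ids)
  data.frame(id = ids,
             exchanges = don + rec,
             as_receiver = rec,
             as_donor = don,
             time_total = td + tr,
             time_as_receiver = tr,
             time_as_donor = td,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summed focal-group connections to a target set
#'
#' Aggregates [connection_to_targets()] over a focal node set. Focal and
#' target sets must be disjoint.
#'
#' @param net A `colony_network`.
#' @param focal Character vector of focal node ids.
#' @param targets Character vector of target node ids.
#' @return One-row data frame of summed counts and durations.
#' @export
group_connection_summary <- function(net, focal, targets) {
  if (length(intersect(focal, targets)) > 0)
    stop("focal and target sets overlap: ",
         paste(intersect(focal, targets), collapse = ", "), call. = FALSE)
  ct <- connection_to_targets(net, targets)
  rows <- ct[ct$id %in% focal, -1, drop = FALSE]
  as.data.frame(t(colSums(rows)))
}

#' Full per-node measure table
#'
#' Degree/strength plus betweenness and eigenvector centrality in one table.
#' Eigenvector is `NA` on an edgeless network.
#'
#' @param net A `colony_network`.
#' @param betweenness_use_weights Passed to [betweenness_centrality()].
#' @param eigen_undirected,eigen_use_weights Passed to
#'   [eigenvector_centrality()].
#' @return Data frame keyed by `id`.
#' @export
node_metrics <- function(net, betweenness_use_weights = FALSE,
                         eigen_undirected = TRUE, eigen_use_weights = TRUE) {
  mt <- degree_strength(net)
  mt$betweenness <- unname(betweenness_centrality(net, betweenness_use_weights)[mt$id])
  ev <- if (nrow(net$edges) > 0) {
    eigenvector_centrality(net, eigen_undirected, eigen_use_weights)[mt$id]
  } else rep(NA_real_, nrow(mt))
  mt$eigenvector <- unname(ev)
  mt
}
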
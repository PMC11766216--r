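# Node-permutation significance framework. Attribute labels are shuffled
# among nodes (optionally within a restricted subset) while the network and
# the per-node measure values stay fixed, which uncouples phenotype from
# network position; the observed statistic is compared against the shuffled
# null with a per-tail 2.5% rule.

#' Group-difference coefficient
#'
#' The least-squares slope of a linear model regressing a per-node measure on
#' the binary group indicator, with the reference group coded 1. With a
#' binary predictor this equals `mean(reference) - mean(focal)` exactly, so a
#' positive coefficient means the reference group (non-hygienic middle-aged
#' bees by default) has the larger mean.
#'
#' @param values Named numeric vector of per-node measure values.
#' @param labels Named (or aligned) character vector of group labels.
#' @param focal,reference Labels of the two compared groups.
#' @return The coefficient (difference of group means).
#' @export
group_coefficient <- function(values, labels, focal = "hygienic",
                              reference = "non_hygienic_mab") {
  vf <- values[!is.na(labels) & labels == focal]
  vr <- values[!is.na(labels) & labels == reference]
  if (length(vf) == 0) stop("no nodes labeled '", focal, "'", call. = FALSE)
  if (length(vr) == 0) stop("no nodes labeled '", reference, "'", call. = FALSE)
  mean(vr) - mean(vf)
}

#' Shuffle labels within a restricted node set
#'
#' Uniformly permutes the labels of the nodes in `restricted_set` among
#' themselves, leaving every other label untouched. Group sizes are conserved
#' by construction.
#'
#' @param labels Named vector of node labels.
#' @param restricted_set Node ids whose labels are permuted. Default: all.
#' @return Labels after the shuffle.
#' @export
restricted_shuffle <- function(labels, restricted_set = names(labels)) {
  idx <- match(restricted_set, names(labels))
  if (anyNA(idx))
    stop("restricted_set contains id(s) absent from labels: ",
         paste(restricted_set[is.na(idx)], collapse = ", "), call. = FALSE)
  labels[idx] <- labels[idx][sample.int(length(idx))]
  labels
}

# Assemble a permutation test result with the per-tail empirical p-values.
# With add_one the observed value is counted into both tails (add-one
# estimator), so p can never be exactly zero.
.perm_result <- function(observed, null_values, alpha_per_tail, add_one,
                         seed, statistic, extra = list()) {
  n <- length(null_values)
  if (add_one) {
    p_lower <- (sum(null_values <= observed) + 1) / (n + 1)
    p_upper <- (sum(null_values >= observed) + 1) / (n + 1)
  } else {
    p_lower <- mean(null_values <= observed)
    p_upper <- mean(null_values >= observed)
  }
  p <- min(p_lower, p_upper)
  structure(c(list(observed = observed, null_values = null_values,
                   p_lower = p_lower, p_upper = p_upper, p_reported = p,
                   significant = p < alpha_per_tail, n_perm = n,
                   alpha_per_tail = alpha_per_tail, add_one = add_one,
                   seed = seed, statistic = statistic), extra),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test (", x$statistic, ")\n", sep = "")
  cat(sprintf("  observed = %.6g; null from %d permutations\n", x$observed, x$n_perm))
  cat(sprintf("  p_lower = %.4g, p_upper = %.4g, p = %.4g%s (alpha = %g per tail)\n",
              x$p_lower, x$p_upper, x$p_reported,
              if (x$significant) " *" else "", x$alpha_per_tail))
  invisible(x)
}

#' Restricted node-permutation test of a group difference
#'
#' Compares a per-node measure between two groups with the group-difference
#' coefficient ([group_coefficient()]), against a null built by repeatedly
#' shuffling the group labels within the restricted set (by default the union
#' of the two compared groups, the standard restriction that conserves both
#' group sizes and the rest of the network). Values stay attached to nodes;
#' only labels move. A result is significant when fewer than
#' `alpha_per_tail` (2.5%) of null values lie beyond the observed value in
#' either tail.
#'
#' @param values Per-node measure: a named numeric vector, or a function of a
#'   network (used with `net`).
#' @param labels Named character vector of node group labels.
#' @param focal,reference The two compared group labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param restricted_set Node ids to shuffle among; default
#'   focal-plus-reference nodes. Use `names(labels)` for an unrestricted
#'   shuffle.
#' @param alpha_per_tail Per-tail significance level (default 0.025).
#' @param add_one Count the observed value into both tails (default `TRUE`)?
#' @param net Network passed to `values` when it is a function.
#' @return A `perm_result`.
#' @export
node_permutation_test <- function(values, labels, focal = "hygienic",
                                  reference = "non_hygienic_mab",
                                  n_perm = 1000, seed = NULL,
                                  restricted_set = NULL,
                                  alpha_per_tail = 0.025, add_one = TRUE,
                                  net = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.function(values)) values <- values(net)
  if (is.null(names(values)))
    stop("values must be a named vector keyed by node id", call. = FALSE)
  labels <- labels[names(values)]
  if (is.null(restricted_set))
    restricted_set <- names(values)[!is.na(labels) & labels %in% c(focal, reference)]
  observed <- group_coefficient(values, labels, focal, reference)
  idx <- match(restricted_set, names(values))
  pool <- labels[idx]
  null_values <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lb <- labels
    lb[idx] <- pool[sample.int(length(idx))]
    null_values[b] <- group_coefficient(values, lb, focal, reference)
  }
  .perm_result(observed, null_values, alpha_per_tail, add_one, seed,
               sprintf("mean(%s) - mean(%s), restricted node permutation",
                       reference, focal),
               extra = list(n_focal = sum(labels == focal, na.rm = TRUE),
                            n_reference = sum(labels == reference, na.rm = TRUE)))
}

#' Unrestricted permutation test of assortativity
#'
#' Shuffles a node attribute over all attribute-bearing networked nodes and
#' recomputes assortativity each time, giving a null distribution for the
#' observed assortment. Nodes with unknown attribute values are excluded
#' identically from the observed and every null computation.
#'
#' @param net A `colony_network`.
#' @param attribute Node attribute: column name, named vector, or vector
#'   aligned with `net$nodes`. Default `"age_days"`.
#' @param type `"numeric"` or `"nominal"`; chosen from the attribute type
#'   when `NULL`.
#' @param n_perm,seed,alpha_per_tail,add_one As in [node_permutation_test()].
#' @param weighted Weight edges by event count?
#' @return A `perm_result` with the observed assortativity.
#' @export
assortativity_permutation_test <- function(net, attribute = "age_days",
                                           type = NULL, n_perm = 1000,
                                           seed = NULL, weighted = FALSE,
                                           alpha_per_tail = 0.025,
                                           add_one = TRUE) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- .node_values(net, attribute)
  if (is.logical(v)) v <- ifelse(v, "yes", "no")
  if (is.null(type)) type <- if (is.numeric(v)) "numeric" else "nominal"
  type <- match.arg(type, c("numeric", "nominal"))
  stat <- if (type == "numeric") {
    function(vals) as.numeric(assortativity_numeric(net, vals, weighted = weighted))
  } else {
    function(vals) assortativity_nominal(net, vals, weighted = weighted)
  }
  observed <- stat(v)
  known <- which(!is.na(v))
  null_values <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    vp <- v
    vp[known] <- v[known][sample.int(length(known))]
    null_values[b] <- stat(vp)
  }
  .perm_result(observed, null_values, alpha_per_tail, add_one, seed,
               paste0(type, " assortativity, unrestricted node permutation"))
}
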
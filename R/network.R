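# Network containers. A static network aggregates events per ordered
# (donor, receiver) pair; a temporal network keeps the chronological event
# sequence over the same node set.

.single_colony <- function(events) {
  cid <- unique(events$colony_id)
  if (length(cid) > 1)
    stop("events cover ", length(cid), " colonies (",
         paste(cid, collapse = ", "), "); build one network per colony",
         call. = FALSE)
  if (length(cid) == 0) NA_character_ else cid
}

# Node attribute table for the individuals that appear in >= 1 event.
# Ids absent from the roster are kept as unknown-age workers.
.node_table <- function(ids, roster, hygienic, reference_ages) {
  if (is.null(roster)) roster <- data.frame(id = character(0), age_days = integer(0),
                                            role = character(0))
  m <- match(ids, roster$id)
  age <- roster$age_days[m]
  role <- ifelse(is.na(m), "worker", roster$role[m])
  hyg <- rep(FALSE, length(ids))
  if (!is.null(hygienic)) {
    hv <- hygienic[ids]
    hyg <- !is.na(hv) & hv
  }
  nodes <- data.frame(id = ids, age_days = as.integer(age), role = role,
                      hygienic = hyg, stringsAsFactors = FALSE)
  nodes$group <- classify_groups(nodes, reference_ages)
  nodes
}

#' Label the comparison groups
#'
#' Assigns every node to one of `queen`, `hygienic`, `non_hygienic_mab`
#' (the reference caste: a non-hygienic worker of the reference age, by
#' default 16 days -- the middle-aged within-nest caste) or `other`.
#'
#' @param nodes Node data frame with columns `age_days`, `role`, `hygienic`.
#' @param reference_ages Integer vector of ages (days) defining the
#'   non-hygienic middle-aged reference group. Default 16.
#' @return Character vector of group labels.
#' @export
classify_groups <- function(nodes, reference_ages = 16) {
  grp <- rep("other", nrow(nodes))
  grp[nodes$role == "queen"] <- "queen"
  grp[nodes$role == "worker" & nodes$hygienic] <- "hygienic"
  mab <- nodes$role == "worker" & !nodes$hygienic &
    !is.na(nodes$age_days) & nodes$age_days %in% reference_ages
  grp[mab] <- "non_hygienic_mab"
  grp
}

#' Build the static directed trophallaxis network
#'
#' Every identifiable individual that took part in at least one (filtered)
#' food exchange becomes a node; each ordered (donor, receiver) pair with at
#' least one exchange becomes a directed edge storing the number of exchanges
#' and their total duration. Individuals that never exchanged food are not in
#' the network.
#'
#' @param events Filtered event data frame (see [filter_short_events()]).
#' @param roster Optional roster for node attributes; ids missing from it are
#'   kept as unknown-age workers.
#' @param hygienic Optional named logical from [code_hygienic_status()].
#' @param reference_ages Passed to [classify_groups()].
#' @return A `colony_network`: list with `nodes`, `edges`, `colony_id`.
#' @export
build_static_network <- function(events, roster = NULL, hygienic = NULL,
                                 reference_ages = 16) {
  stopifnot(is.data.frame(events))
  cid <- .single_colony(events)
  if (nrow(events) == 0) {
    nodes <- .node_table(character(0), roster, hygienic, reference_ages)
    edges <- data.frame(donor = character(0), receiver = character(0),
                        n_events = integer(0), total_duration = numeric(0))
  } else {
    ids <- sort(unique(c(events$donor_id, events$receiver_id)))
    k <- factor(paste(events$donor_id, events$receiver_id, sep = "\x1f"))
    dur <- rowsum(events$duration, k)  # rows in level order
    pair <- strsplit(levels(k), "\x1f", fixed = TRUE)
    edges <- data.frame(
      donor = vapply(pair, `[`, character(1), 1L),
      receiver = vapply(pair, `[`, character(1), 2L),
      n_events = tabulate(k),
      total_duration = as.numeric(dur),
      stringsAsFactors = FALSE
    )
    nodes <- .node_table(ids, roster, hygienic, reference_ages)
  }
  structure(list(nodes = nodes, edges = edges, colony_id = cid),
            class = "colony_network")
}

#' Build the time-ordered trophallaxis network
#'
#' Keeps the full chronological event sequence for dynamic (time-respecting)
#' analyses. Events are stably sorted by start time, so simultaneous events
#' keep their input order; every event must start within the observation
#' horizon.
#'
#' @inheritParams build_static_network
#' @param horizon Observation end time in seconds (default 3600, one hour of
#'   footage). Must be at least the latest event start time.
#' @return A `colony_temporal`: list with `nodes`, `events` (sorted),
#'   `horizon`, `colony_id`.
#' @export
build_temporal_network <- function(events, roster = NULL, hygienic = NULL,
                                   horizon = 3600, reference_ages = 16) {
  stopifnot(is.data.frame(events))
  cid <- .single_colony(events)
  if (nrow(events) > 0 && max(events$start_time) > horizon)
    stop("event(s) start after the observation horizon (", horizon, " s)",
         call. = FALSE)
  ord <- order(events$start_time)  # stable: ties keep input order
  ev <- events[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ids <- if (nrow(ev) > 0) sort(unique(c(ev$donor_id, ev$receiver_id))) else character(0)
  nodes <- .node_table(ids, roster, hygienic, reference_ages)
  structure(list(nodes = nodes, events = ev, horizon = horizon, colony_id = cid),
            class = "colony_temporal")
}

#' Convert a static network to an igraph object
#'
#' Edge attributes `n_events` and `total_duration` are carried over; with
#' `undirected = TRUE` reciprocal edges are collapsed and their attributes
#' summed (the symmetrized adjacency).
#'
#' @param net A `colony_network`.
#' @param undirected Collapse to an undirected graph?
#' @return An igraph graph.
#' @export
as_igraph <- function(net, undirected = FALSE) {
  stopifnot(inherits(net, "colony_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("donor", "receiver", "n_events", "total_duration")],
    directed = TRUE, vertices = net$nodes)
  if (undirected)
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(n_events = "sum",
                                                     total_duration = "sum"))
  g
}

#' @export
print.colony_network <- function(x, ...) {
  cat("Trophallaxis network (colony ", x$colony_id, "): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " directed edges, ",
      sum(x$edges$n_events), " exchanges\n", sep = "")
  tg <- table(x$nodes$group)
  cat("  groups:", paste(names(tg), tg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.colony_temporal <- function(x, ...) {
  cat("Time-ordered trophallaxis network (colony ", x$colony_id, "): ",
      nrow(x$nodes), " nodes, ", nrow(x$events), " events, horizon ",
      x$horizon, " s\n", sep = "")
  invisible(x)
}
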
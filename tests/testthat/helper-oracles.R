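# Fixture builders and independent brute-force oracles used across the suite.

# Compact event-frame constructor.
ev_df <- function(donor, receiver, start, duration = 3, colony = "c1") {
  if (length(donor) == 0)
    return(data.frame(colony_id = character(0), donor_id = character(0),
                      receiver_id = character(0), start_time = numeric(0),
                      duration = numeric(0)))
  data.frame(colony_id = colony, donor_id = donor, receiver_id = receiver,
             start_time = start, duration = rep_len(duration, length(donor)),
             stringsAsFactors = FALSE)
}

roster_df <- function(id, age = NA_integer_, role = "worker", colony = "c1") {
  data.frame(colony_id = colony, id = id,
             age_days = as.integer(rep_len(age, length(id))),
             role = rep_len(role, length(id)), stringsAsFactors = FALSE)
}

acts_df <- function(id, task = "uncap", time = -100, colony = "c1") {
  n <- max(length(id), length(task), length(time))
  if (n == 0)
    return(data.frame(colony_id = character(0), id = character(0),
                      task = character(0), act_time = numeric(0)))
  data.frame(colony_id = colony, id = rep_len(id, n),
             task = rep_len(task, n), act_time = rep_len(time, n),
             stringsAsFactors = FALSE)
}

# Random simple digraph on n nodes with m distinct ordered pairs.
random_digraph_events <- function(n, m) {
  ids <- letters[seq_len(n)]
  pairs <- expand.grid(d = ids, r = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$d != pairs$r, ]
  take <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ]
  ev_df(take$d, take$r, start = seq_len(nrow(take)), duration = 2 + seq_len(nrow(take)))
}

# Random temporal network: k events among n nodes at distinct times.
random_temporal_events <- function(n, k) {
  ids <- letters[seq_len(n)]
  d <- character(k); r <- character(k)
  for (i in seq_len(k)) {
    p <- sample(ids, 2)
    d[i] <- p[1]; r[i] <- p[2]
  }
  ev_df(d, r, start = sample(seq_len(100 * k), k), duration = 3)
}

# Exhaustive betweenness by enumerating all simple paths (directed,
# unweighted): for every ordered pair, all shortest paths are listed and
# interior nodes tallied with fractional credit.
oracle_betweenness <- function(net) {
  ids <- net$nodes$id
  adj <- lapply(setNames(ids, ids), function(v)
    net$edges$receiver[net$edges$donor == v])
  btw <- setNames(numeric(length(ids)), ids)
  all_paths <- function(cur, target, visited) {
    if (cur == target) return(list(visited))
    out <- list()
    for (nxt in adj[[cur]])
      if (!(nxt %in% visited))
        out <- c(out, all_paths(nxt, target, c(visited, nxt)))
    out
  }
  for (s in ids) for (t in ids) {
    if (s == t) next
    ps <- all_paths(s, t, s)
    if (length(ps) == 0) next
    len <- vapply(ps, length, integer(1))
    sp <- ps[len == min(len)]
    if (min(len) <= 2) next
    inter <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    tb <- table(inter)
    btw[names(tb)] <- btw[names(tb)] + as.numeric(tb) / length(sp)
  }
  btw
}

# Dense linear-algebra eigenvector oracle on the symmetrized weighted
# adjacency, max-normalized.
oracle_eigen <- function(net, weighted = TRUE) {
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges)))
    A[net$edges$donor[i], net$edges$receiver[i]] <-
      if (weighted) net$edges$total_duration[i] else 1
  S <- A + t(A)
  e <- eigen(S, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

# Time-respecting reach by fixpoint relaxation over strictly increasing
# times (valid when all event times are distinct).
oracle_reach <- function(events, seed_id, mode) {
  ids <- sort(unique(c(events$donor_id, events$receiver_id)))
  inf_t <- setNames(rep(Inf, length(ids)), ids)
  inf_t[seed_id] <- -Inf
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(events))) {
      d <- events$donor_id[i]; r <- events$receiver_id[i]
      t <- events$start_time[i]
      if (inf_t[[d]] < t && inf_t[[r]] > t) { inf_t[r] <- t; changed <- TRUE }
      if (mode == "both" && inf_t[[r]] < t && inf_t[[d]] > t) {
        inf_t[d] <- t; changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(setdiff(ids[inf_t < Inf], seed_id))
}

# One full generate -> filter -> code -> network -> time-as-donor
# permutation test replicate; returns the reported p (NA if a focal group
# is empty in the network).
replicate_donor_test <- function(delta, seed, n_perm = 200) {
  cfg <- colony_config(effect_delta = delta)
  col <- generate_colony(cfg, seed = seed)
  ev <- filter_short_events(col$events)
  hyg <- suppressMessages(code_hygienic_status(col$roster, col$acts, ev))
  net <- build_static_network(ev, col$roster, hyg)
  labels <- setNames(net$nodes$group, net$nodes$id)
  if (sum(labels == "hygienic") == 0 || sum(labels == "non_hygienic_mab") == 0)
    return(NA_real_)
  mt <- degree_strength(net)
  node_permutation_test(setNames(mt$time_as_donor, mt$id), labels,
                        n_perm = n_perm)$p_reported
}
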
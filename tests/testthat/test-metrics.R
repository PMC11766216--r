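test_that("degree and strength split events and durations by direction", {
  ev <- ev_df(c("A", "A", "B"), c("B", "B", "A"), c(1, 2, 3), duration = c(3, 4, 2))
  mt <- degree_strength(build_static_network(ev))
  a <- mt[mt$id == "A", ]
  expect_equal(a$donations, 2)
  expect_equal(a$receptions, 1)
  expect_equal(a$time_as_donor, 7)
  expect_equal(a$time_as_receiver, 2)
  expect_equal(a$exchanges_total, 3)
  expect_equal(a$time_total, 9)

  # flow conservation on a generated network
  col <- generate_colony(colony_config(), seed = 9)
  net <- build_static_network(filter_short_events(col$events))
  mt <- degree_strength(net)
  expect_equal(sum(mt$donations), sum(mt$receptions))
  expect_equal(sum(mt$donations), nrow(filter_short_events(col$events)))
  expect_equal(mt$exchanges_total, mt$receptions + mt$donations)
  expect_equal(mt$time_total, mt$time_as_receiver + mt$time_as_donor)

  # simple-graph variant counts distinct partners
  mp <- degree_strength(build_static_network(ev), count = "partners")
  expect_equal(mp[mp$id == "A", "donations"], 1)
})

test_that("betweenness matches hand values and the exhaustive path oracle", {
  path <- build_static_network(ev_df(c("a", "b"), c("b", "c"), c(1, 2)))
  b <- betweenness_centrality(path)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  tri <- build_static_network(
    ev_df(c("a", "a", "b", "b", "c", "c"), c("b", "c", "a", "c", "a", "b"),
          seq_len(6)))
  expect_equal(unname(betweenness_centrality(tri)), c(0, 0, 0))

  set.seed(21)
  for (i in 1:40) {
    net <- build_static_network(
      random_digraph_events(sample(4:6, 1), sample(4:10, 1)))
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-12)
  }
})

test_that("eigenvector centrality matches symmetry expectations and scales to 1", {
  star <- build_static_network(
    ev_df(c("hub", "hub", "hub"), c("l1", "l2", "l3"), 1:3, duration = 5))
  v <- eigenvector_centrality(star)
  expect_equal(unname(v["hub"]), 1)
  expect_equal(unname(v["l1"]), unname(v["l2"]))
  expect_lt(v[["l1"]], 1)

  dyads <- build_static_network(
    ev_df(c("a", "c"), c("b", "d"), 1:2, duration = c(4, 4)))
  v <- eigenvector_centrality(dyads)
  expect_equal(v[["a"]], v[["b"]])
  expect_equal(v[["c"]], v[["d"]])

  expect_error(eigenvector_centrality(build_static_network(ev_df(character(0), character(0), numeric(0)))),
               "at least one edge")
})

test_that("eigenvector centrality matches dense eigen-decomposition and is scale invariant", {
  set.seed(33)
  mk <- function(scale = 1) {
    ids <- letters[1:6]
    d <- c("a", "b", "c", "d", "e", "a", "b", "c")
    r <- c("b", "c", "d", "e", "f", "c", "d", "f")
    ev_df(d, r, seq_along(d), duration = scale * c(3, 7, 2, 9, 4, 5, 6, 8))
  }
  net <- build_static_network(mk())
  expect_equal(eigenvector_centrality(net), setNames(oracle_eigen(net), net$nodes$id),
               tolerance = 1e-6)
  # invariance under uniform weight scaling
  net10 <- build_static_network(mk(scale = 10))
  expect_equal(eigenvector_centrality(net10), eigenvector_centrality(net),
               tolerance = 1e-6)
  # random connected weighted graphs against the dense oracle
  for (i in 1:20) {
    n <- sample(4:7, 1)
    ids <- letters[1:n]
    d <- ids[seq_len(n - 1)]; r <- ids[2:n]            # path: connected
    extra <- sample(n, 2)
    ev <- ev_df(c(d, ids[extra[1]]), c(r, ids[extra[2] %% n + 1]),
                seq_len(n), duration = runif(n, 2, 20))
    ev <- ev[ev$donor_id != ev$receiver_id, ]
    net <- build_static_network(ev)
    expect_equal(eigenvector_centrality(net),
                 setNames(oracle_eigen(net), net$nodes$id), tolerance = 1e-6)
  }
})

test_that("edge density counts distinct ordered pairs over N(N-1)", {
  ids <- c("a", "b", "c", "d")
  full <- expand.grid(d = ids, r = ids, stringsAsFactors = FALSE)
  full <- full[full$d != full$r, ]
  net <- build_static_network(ev_df(full$d, full$r, seq_len(nrow(full))))
  expect_equal(edge_density(net), 1)

  sub <- build_static_network(ev_df(c("a", "b", "c"), c("b", "c", "d"), 1:3))
  expect_equal(edge_density(sub), 3 / 12)
  # adding a new ordered pair strictly increases density
  sub2 <- build_static_network(ev_df(c("a", "b", "c", "d"), c("b", "c", "d", "a"), 1:4))
  expect_gt(edge_density(sub2), edge_density(sub))

  expect_error(edge_density(build_static_network(ev_df(character(0), character(0), numeric(0)))),
               "fewer than 2 nodes")
})

test_that("nominal assortativity reproduces the mixing-matrix formula", {
  # all edges within-category
  ev <- ev_df(c("a", "b", "c", "d"), c("b", "a", "d", "c"), 1:4)
  net <- build_static_network(ev)
  lab <- c(a = "x", b = "x", c = "y", d = "y")
  expect_equal(assortativity_nominal(net, lab), 1)

  # purely bipartite mixing between two equal categories
  ev <- ev_df(c("a", "b", "c", "d"), c("c", "d", "a", "b"), 1:4)
  expect_equal(assortativity_nominal(build_static_network(ev), lab), -1)

  # single category is undefined
  expect_error(assortativity_nominal(build_static_network(ev),
                                     c(a = "x", b = "x", c = "x", d = "x")),
               "single category")

  # category relabeling leaves the coefficient unchanged
  set.seed(44)
  ev <- random_digraph_events(8, 14)
  net <- build_static_network(ev)
  lab <- setNames(sample(c("u", "v", "w"), nrow(net$nodes), replace = TRUE),
                  net$nodes$id)
  relab <- c(u = "v", v = "w", w = "u")[lab]
  names(relab) <- names(lab)
  expect_equal(assortativity_nominal(net, lab), assortativity_nominal(net, relab))
})

test_that("numeric assortativity is the endpoint-value correlation over directed edges", {
  ev <- ev_df(c("a", "b", "c", "d", "a", "c", "b", "d"),
              c("b", "a", "d", "c", "c", "a", "d", "b"), 1:8)
  net <- build_static_network(ev)
  vals <- c(a = 1, b = 2, c = 5, d = 7)
  vd <- vals[ev$donor_id]; vr <- vals[ev$receiver_id]
  expect_equal(as.numeric(assortativity_numeric(net, vals)), cor(vd, vr))

  # equal-valued endpoints only -> +1
  ev <- ev_df(c("a", "c"), c("b", "d"), 1:2)
  expect_equal(as.numeric(assortativity_numeric(build_static_network(ev),
                                                c(a = 1, b = 1, c = 9, d = 9))), 1)

  expect_error(assortativity_numeric(build_static_network(ev),
                                     c(a = 1, b = 1, c = 1, d = 1)),
               "zero variance")

  # unknown-age endpoints are excluded and counted
  ev <- ev_df(c("a", "b", "c", "q"), c("b", "c", "a", "a"), 1:4)
  r <- assortativity_numeric(build_static_network(ev),
                             c(a = 1, b = 2, c = 3, q = NA))
  expect_equal(attr(r, "n_edges_excluded"), 1L)
})

test_that("values independent of topology give near-zero numeric assortativity", {
  set.seed(55)
  hits <- 0L
  for (i in 1:40) {
    ids <- sprintf("n%02d", 1:60)
    d <- sample(ids, 500, replace = TRUE)
    r <- sample(ids, 500, replace = TRUE)
    keep <- d != r
    net <- build_static_network(ev_df(d[keep], r[keep], seq_len(sum(keep))))
    vals <- setNames(rnorm(length(net$nodes$id)), net$nodes$id)
    if (abs(assortativity_numeric(net, vals)) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("target-connection summaries match a brute-force scan of raw events", {
  ev <- ev_df(c("h1", "q", "h2", "w1"), c("q", "h1", "w1", "h1"),
              1:4, duration = c(5, 3, 4, 6))
  net <- build_static_network(ev)

  s <- group_connection_summary(net, focal = "h1", targets = "q")
  expect_equal(s$as_donor, 1)
  expect_equal(s$time_as_donor, 5)
  expect_equal(s$as_receiver, 1)
  expect_equal(s$time_as_receiver, 3)

  expect_equal(group_connection_summary(net, "h2", "q")$exchanges, 0)
  expect_error(group_connection_summary(net, c("h1", "q"), "q"), "overlap")

  # generated network: equality with an independent scan over raw events
  col <- generate_colony(colony_config(), seed = 13)
  ev <- filter_short_events(col$events)
  net <- build_static_network(ev, col$roster)
  young <- col$roster$id[!is.na(col$roster$age_days) & col$roster$age_days == 2]
  targets <- intersect(c("queen", young), net$nodes$id)
  focal <- setdiff(sample(net$nodes$id, 40), targets)
  s <- group_connection_summary(net, focal, targets)
  don <- ev$donor_id %in% focal & ev$receiver_id %in% targets
  rec <- ev$receiver_id %in% focal & ev$donor_id %in% targets
  expect_equal(s$as_donor, sum(don))
  expect_equal(s$as_receiver, sum(rec))
  expect_equal(s$time_as_donor, sum(ev$duration[don]))
  expect_equal(s$time_as_receiver, sum(ev$duration[rec]))
  expect_equal(s$exchanges, sum(don) + sum(rec))
})
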
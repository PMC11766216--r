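# End-to-end analyses and file-based front ends: colony summary, the two
# group-comparison tables, assortativity tests, the spread report, and the
# cmd_* functions that wire files in and delimited tables out.

.pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Summary of a colony network and its hygienic workers
#'
#' Basic structure of the network (nodes, edges, density, longest single
#' exchange) together with the hygienic-worker census: how many workers were
#' coded hygienic, their task profiles (uncap only / remove only / both),
#' mean and SD age per task, and how many of each focal group made it into
#' the network.
#'
#' @param events Filtered event data frame.
#' @param roster Roster data frame.
#' @param acts Hygienic act data frame.
#' @param net Optional prebuilt `colony_network` (built from the inputs when
#'   `NULL`).
#' @param hygienic Optional precomputed flags from [code_hygienic_status()].
#' @param reference_ages Reference ages for the non-hygienic middle-aged group.
#' @return A `colony_summary` list.
#' @export
summarize_colony <- function(events, roster, acts, net = NULL, hygienic = NULL,
                             reference_ages = 16) {
  if (is.null(hygienic)) hygienic <- code_hygienic_status(roster, acts, events)
  if (is.null(net)) net <- build_static_network(events, roster, hygienic,
                                                reference_ages)
  hyg_ids <- names(hygienic)[hygienic]
  tasks_of <- function(id) unique(acts$task[acts$id == id])
  prof <- vapply(hyg_ids, function(id) {
    tk <- tasks_of(id)
    if (length(tk) == 2) "both" else tk
  }, character(1))
  n_h <- length(hyg_ids)
  age_of <- roster$age_days[match(hyg_ids, roster$id)]
  age_task <- function(task) {
    a <- age_of[vapply(hyg_ids, function(id) task %in% tasks_of(id), logical(1))]
    a <- a[!is.na(a)]
    c(mean = if (length(a)) mean(a) else NA_real_,
      sd = if (length(a) > 1) sd(a) else NA_real_)
  }
  in_net <- hyg_ids[hyg_ids %in% net$nodes$id]
  structure(list(
    colony_id = net$colony_id,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_exchanges = sum(net$edges$n_events),
    max_duration = if (nrow(events)) max(events$duration) else NA_real_,
    density = if (nrow(net$nodes) >= 2) edge_density(net) else NA_real_,
    n_hygienic_total = n_h,
    n_uncap_only = sum(prof == "uncap"),
    pct_uncap_only = .pct(sum(prof == "uncap"), n_h),
    n_remove_only = sum(prof == "remove"),
    pct_remove_only = .pct(sum(prof == "remove"), n_h),
    n_both = sum(prof == "both"),
    pct_both = .pct(sum(prof == "both"), n_h),
    age_uncap_mean = age_task("uncap")[["mean"]],
    age_uncap_sd = age_task("uncap")[["sd"]],
    age_remove_mean = age_task("remove")[["mean"]],
    age_remove_sd = age_task("remove")[["sd"]],
    n_hygienic_in_network = length(in_net),
    pct_hygienic_in_network = .pct(length(in_net), n_h),
    n_mab_in_network = sum(net$nodes$group == "non_hygienic_mab")
  ), class = "colony_summary")
}

#' @export
print.colony_summary <- function(x, ...) {
  cat("Colony ", x$colony_id, ": ", x$n_nodes, " nodes, ", x$n_edges,
      " edges (", x$n_exchanges, " exchanges), density ",
      signif(x$density, 3), ", max duration ", x$max_duration, " s\n", sep = "")
  cat(sprintf("  hygienic workers: %d (uncap only %d, remove only %d, both %d); %d (%.1f%%) in network; %d non-hygienic middle-aged in network\n",
              x$n_hygienic_total, x$n_uncap_only, x$n_remove_only, x$n_both,
              x$n_hygienic_in_network, x$pct_hygienic_in_network,
              x$n_mab_in_network))
  invisible(x)
}

.check_groups <- function(labels, focal, reference) {
  for (g in c(focal, reference))
    if (sum(labels == g, na.rm = TRUE) == 0)
      stop("no networked nodes in group '", g,
           "'; cannot run the group comparison", call. = FALSE)
}

.comparison_row <- function(values, labels, focal, reference, n_perm,
                            alpha_per_tail, add_one) {
  pr <- node_permutation_test(values, labels, focal, reference, n_perm = n_perm,
                              alpha_per_tail = alpha_per_tail, add_one = add_one)
  vf <- values[!is.na(labels) & labels == focal]
  vr <- values[!is.na(labels) & labels == reference]
  data.frame(focal_n = length(vf), focal_sum = sum(vf),
             focal_median = median(vf),
             reference_n = length(vr), reference_sum = sum(vr),
             reference_median = median(vr),
             coefficient = pr$observed, p = pr$p_reported,
             significant = pr$significant)
}

#' Group comparison over the full measure suite
#'
#' The eight-measure centrality comparison between hygienic workers and
#' non-hygienic middle-aged bees: the six degree/strength measures plus
#' betweenness and eigenvector centrality, each tested with the restricted
#' node-permutation test. Sums and medians per group are reported alongside
#' the coefficient and permutation p-value.
#'
#' @param net A `colony_network`.
#' @param n_perm Permutations per measure.
#' @param seed Optional seed set once before the whole table.
#' @param focal,reference Compared group labels.
#' @param betweenness_use_weights,eigen_undirected,eigen_use_weights Metric
#'   variants, see [node_metrics()].
#' @param alpha_per_tail,add_one See [node_permutation_test()].
#' @return Data frame with one row per measure.
#' @export
compare_groups <- function(net, n_perm = 1000, seed = NULL,
                           focal = "hygienic", reference = "non_hygienic_mab",
                           betweenness_use_weights = FALSE,
                           eigen_undirected = TRUE, eigen_use_weights = TRUE,
                           alpha_per_tail = 0.025, add_one = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  labels <- setNames(net$nodes$group, net$nodes$id)
  .check_groups(labels, focal, reference)
  mt <- node_metrics(net, betweenness_use_weights, eigen_undirected,
                     eigen_use_weights)
  measures <- c(exchanges_total = "Total nectar exchanges",
                receptions = "As receiver",
                donations = "As donor",
                time_total = "Total time",
                time_as_receiver = "Time as receiver",
                time_as_donor = "Time as donor",
                betweenness = "Betweenness",
                eigenvector = "Eigenvector")
  rows <- lapply(names(measures), function(m) {
    v <- setNames(mt[[m]], mt$id)
    cbind(data.frame(measure = m, label = measures[[m]]),
          .comparison_row(v, labels, focal, reference, n_perm,
                          alpha_per_tail, add_one))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Queen-and-young-workers connection comparison
#'
#' Compares hygienic and non-hygienic middle-aged workers on their direct
#' connections to the colony's most valuable members: the queen plus the
#' youngest cohort. Six per-node measures (exchange counts and durations with
#' the target set, split by direction) are each tested with the restricted
#' node-permutation test. Focal-group members are never targets.
#'
#' @param net A `colony_network`.
#' @param young_age Age(s) in days defining the young cohort (default 2).
#' @inheritParams compare_groups
#' @return Data frame with one row per measure; the target set is attached
#'   as attribute `targets`.
#' @export
compare_target_connections <- function(net, young_age = 2, n_perm = 1000,
                                       seed = NULL, focal = "hygienic",
                                       reference = "non_hygienic_mab",
                                       alpha_per_tail = 0.025, add_one = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  nd <- net$nodes
  targets <- nd$id[nd$group == "queen" |
                     (!is.na(nd$age_days) & nd$age_days %in% young_age &
                        !nd$group %in% c("hygienic", "non_hygienic_mab"))]
  if (length(targets) == 0)
    stop("no queen or young workers in the network to act as targets",
         call. = FALSE)
  labels <- setNames(nd$group, nd$id)
  .check_groups(labels, focal, reference)
  ct <- connection_to_targets(net, targets)
  labels <- labels[ct$id]
  measures <- c(exchanges = "Nectar exchanges",
                as_receiver = "As receiver",
                as_donor = "As donor",
                time_total = "Total time",
                time_as_receiver = "Time as receiver",
                time_as_donor = "Time as donor")
  rows <- lapply(names(measures), function(m) {
    v <- setNames(ct[[m]], ct$id)
    cbind(data.frame(measure = m, label = measures[[m]]),
          .comparison_row(v, labels, focal, reference, n_perm,
                          alpha_per_tail, add_one))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "targets") <- targets
  out
}

#' Assortativity tests for hygienic status and age
#'
#' Unrestricted node-permutation tests of nominal assortativity by hygienic
#' status and numeric assortativity by age (unknown-age nodes excluded).
#'
#' @param net A `colony_network`.
#' @param n_perm,seed,alpha_per_tail,add_one See
#'   [assortativity_permutation_test()].
#' @return List with `perm_result` elements `hygienic` and `age`.
#' @export
assortativity_tests <- function(net, n_perm = 1000, seed = NULL,
                                alpha_per_tail = 0.025, add_one = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  list(
    hygienic = assortativity_permutation_test(net, attribute = "hygienic",
                                              type = "nominal", n_perm = n_perm,
                                              alpha_per_tail = alpha_per_tail,
                                              add_one = add_one),
    age = assortativity_permutation_test(net, attribute = "age_days",
                                         type = "numeric", n_perm = n_perm,
                                         alpha_per_tail = alpha_per_tail,
                                         add_one = add_one)
  )
}

#' Full static-network analysis of one colony
#'
#' Filters short exchanges, codes hygienic status, builds the network and
#' produces the colony summary, the eight-measure group comparison, the
#' queen-and-young comparison, and both assortativity tests.
#'
#' @param events Raw event data frame (unfiltered).
#' @param roster,acts Roster and act data frames.
#' @param n_perm Permutations for every test.
#' @param seed Seed set once for the whole analysis.
#' @param min_duration Exchange duration threshold in seconds.
#' @param reference_ages,young_age Group definitions.
#' @return List with `summary`, `centrality`, `targets`, `assortativity`,
#'   `network`, and the flags/settings used.
#' @export
analyze_colony <- function(events, roster, acts, n_perm = 1000, seed = NULL,
                           min_duration = 2, reference_ages = 16,
                           young_age = 2) {
  if (!is.null(seed)) set.seed(seed)
  ev <- filter_short_events(events, min_duration)
  hygienic <- code_hygienic_status(roster, acts, ev)
  net <- build_static_network(ev, roster, hygienic, reference_ages)
  list(summary = summarize_colony(ev, roster, acts, net, hygienic,
                                  reference_ages),
       centrality = compare_groups(net, n_perm = n_perm),
       targets = compare_target_connections(net, young_age = young_age,
                                            n_perm = n_perm),
       assortativity = assortativity_tests(net, n_perm = n_perm),
       network = net,
       settings = list(n_perm = n_perm, seed = seed,
                       min_duration = min_duration,
                       reference_ages = reference_ages, young_age = young_age))
}

#' Spread report for one colony
#'
#' Per-seed reached fractions, the maximum-reach summary, and the
#' time-permutation comparison of spread potential between hygienic and
#' non-hygienic middle-aged workers.
#'
#' @param tnet A `colony_temporal`.
#' @param mode Transmission mode, see [time_respecting_reach()].
#' @param n_perm,seed See [spread_potential_test()].
#' @return List with `spread` (a `spread_result`), `test` (a `perm_result`),
#'   and `mode`.
#' @export
spread_report <- function(tnet, mode = c("both", "forward"), n_perm = 1000,
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  list(spread = spread_analysis(tnet, mode),
       test = spread_potential_test(tnet, mode = mode, n_perm = n_perm),
       mode = mode)
}

# --- file-based front ends -------------------------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

.manifest <- function(out_dir, inputs, settings) {
  md5 <- if (length(inputs)) tools::md5sum(inputs) else character(0)
  df <- data.frame(
    key = c("trophnet_version", paste0("md5_", basename(names(md5))),
            names(settings)),
    value = c(as.character(utils::packageVersion("trophnet")),
              unname(md5),
              vapply(settings, function(s) paste(s, collapse = ","), character(1))),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, file.path(out_dir, "manifest.tsv"))
}

#' Simulate a colony to files
#'
#' Generates a synthetic colony and writes the event log, roster, acts,
#' ground truth and configuration in the package's interchange formats.
#'
#' @param config A [colony_config()], or the path of a configuration file
#'   written by [write_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed; the same seed reproduces the files byte for byte.
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(config = colony_config(), out_dir, seed = 1) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  col <- generate_colony(config, seed = seed)
  paths <- c(events = file.path(out_dir, "events.csv"),
             roster = file.path(out_dir, "roster.csv"),
             acts = file.path(out_dir, "acts.csv"),
             truth = file.path(out_dir, "truth.txt"),
             config = file.path(out_dir, "config.txt"))
  write_event_log(col$events, paths[["events"]])
  write_roster(col$roster, paths[["roster"]])
  write_acts(col$acts, paths[["acts"]])
  write_truth(col$truth, paths[["truth"]])
  write_config(config, paths[["config"]])
  net <- build_static_network(col$events)
  message(sprintf("simulated colony '%s': %d events, %d networked individuals, density %.4g",
                  config$colony_id, nrow(col$events), nrow(net$nodes),
                  edge_density(net)))
  .manifest(out_dir, unname(paths[c("events", "roster", "acts")]),
            list(command = "simulate", seed = seed))
  invisible(paths)
}

#' Analyze a colony from files
#'
#' Reads the event log, roster and acts, runs [analyze_colony()] and writes
#' the summary, both comparison tables, the assortativity results and a run
#' manifest as tab-delimited text.
#'
#' @param events_path,roster_path,acts_path Input files.
#' @param out_dir Output directory.
#' @param n_perm,seed,min_duration,reference_ages,young_age Passed to
#'   [analyze_colony()].
#' @return The [analyze_colony()] result, invisibly.
#' @export
cmd_analyze <- function(events_path, roster_path, acts_path, out_dir,
                        n_perm = 1000, seed = 1, min_duration = 2,
                        reference_ages = 16, young_age = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_colony(read_event_log(events_path), read_roster(roster_path),
                        read_acts(acts_path), n_perm = n_perm, seed = seed,
                        min_duration = min_duration,
                        reference_ages = reference_ages, young_age = young_age)
  s <- res$summary
  .write_tsv(data.frame(key = names(unclass(s)),
                        value = vapply(unclass(s), function(v)
                          paste(format(v, digits = 10), collapse = ","),
                          character(1))),
             file.path(out_dir, "summary.tsv"))
  .write_tsv(res$centrality, file.path(out_dir, "centrality_comparison.tsv"))
  .write_tsv(res$targets, file.path(out_dir, "target_comparison.tsv"))
  at <- res$assortativity
  .write_tsv(data.frame(
    attribute = c("hygienic", "age"),
    observed = c(at$hygienic$observed, at$age$observed),
    p_lower = c(at$hygienic$p_lower, at$age$p_lower),
    p_upper = c(at$hygienic$p_upper, at$age$p_upper),
    p = c(at$hygienic$p_reported, at$age$p_reported),
    significant = c(at$hygienic$significant, at$age$significant),
    n_perm = n_perm
  ), file.path(out_dir, "assortativity.tsv"))
  .manifest(out_dir, c(events_path, roster_path, acts_path),
            list(command = "analyze", seed = seed, n_perm = n_perm,
                 min_duration = min_duration, reference_ages = reference_ages,
                 young_age = young_age,
                 coefficient = "mean(non_hygienic_mab) - mean(hygienic)",
                 multiple_testing_correction = "none"))
  invisible(res)
}

#' Spread analysis from files
#'
#' Reads the inputs, builds the time-ordered network and writes per-seed
#' reached fractions, per-seed infection trajectories, the group spread test
#' and a run manifest.
#'
#' @inheritParams cmd_analyze
#' @param mode Transmission mode (`"both"` or `"forward"`), recorded in the
#'   manifest.
#' @param horizon Observation horizon in seconds.
#' @return The [spread_report()] result, invisibly.
#' @export
cmd_spread <- function(events_path, roster_path, acts_path, out_dir,
                       mode = "both", n_perm = 1000, seed = 1,
                       min_duration = 2, horizon = 3600,
                       reference_ages = 16) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- filter_short_events(read_event_log(events_path), min_duration)
  roster <- read_roster(roster_path)
  acts <- read_acts(acts_path)
  hygienic <- code_hygienic_status(roster, acts, events)
  tnet <- build_temporal_network(events, roster, hygienic, horizon,
                                 reference_ages)
  res <- spread_report(tnet, mode = mode, n_perm = n_perm, seed = seed)
  .write_tsv(res$spread$table, file.path(out_dir, "spread.tsv"))
  traj <- do.call(rbind, lapply(res$spread$table$id, function(id) {
    tr <- time_respecting_reach(tnet, id, mode)$trajectory
    if (nrow(tr) == 0) return(NULL)
    cbind(data.frame(id = id), tr)
  }))
  if (is.null(traj)) traj <- data.frame(id = character(0), time = numeric(0),
                                        cum_reached = integer(0))
  .write_tsv(traj, file.path(out_dir, "trajectories.tsv"))
  t <- res$test
  .write_tsv(data.frame(observed = t$observed, p_lower = t$p_lower,
                        p_upper = t$p_upper, p = t$p_reported,
                        significant = t$significant, n_perm = t$n_perm,
                        mode = mode, max_fraction = res$spread$max_fraction),
             file.path(out_dir, "spread_test.tsv"))
  .manifest(out_dir, c(events_path, roster_path, acts_path),
            list(command = "spread", seed = seed, n_perm = n_perm, mode = mode,
                 min_duration = min_duration, horizon = horizon,
                 reference_ages = reference_ages))
  invisible(res)
}
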
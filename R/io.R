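# Delimited interchange formats. All files carry a mandatory header row and
# are UTF-8; times are seconds from the start of the observation window.
EVENT_COLS  <- c("colony_id", "donor_id", "receiver_id", "start_time_s", "duration_s")
ROSTER_COLS <- c("colony_id", "id", "age_days", "role")
ACT_COLS    <- c("colony_id", "id", "task", "act_time_s")

#' Hygienic task vocabulary
#'
#' The two subtasks of hygienic behavior scored in the data: uncapping a brood
#' cell and removing a dead pupa.
#' @export
HYGIENIC_TASKS <- c("uncap", "remove")

.read_delim_checked <- function(path, cols, sep, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE,
                           na.strings = character(0))
  miss <- setdiff(cols, names(raw))
  if (length(miss) > 0)
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw[cols]
}

.lines <- function(i) paste(i + 1L, collapse = ", ")  # data row i sits on file line i+1

.num_col <- function(x, col, path, positive = FALSE, nonneg = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(x %in% c("NA", "")))
  na <- which(x %in% c("NA", ""))
  bad <- sort(unique(c(bad, na)))
  if (length(bad) > 0)
    stop("non-numeric ", col, " in ", path, " at line(s) ", .lines(bad), call. = FALSE)
  if (positive && any(v <= 0))
    stop(col, " must be > 0 in ", path, " at line(s) ", .lines(which(v <= 0)), call. = FALSE)
  if (nonneg && any(v < 0))
    stop(col, " must be >= 0 in ", path, " at line(s) ", .lines(which(v < 0)), call. = FALSE)
  v
}

#' Read a trophallaxis event log
#'
#' One row per observed nectar exchange: which individual donated, which
#' received, when the exchange started (seconds from the start of filming) and
#' how long it lasted. Rows are validated with file line numbers; the row
#' order of the file is preserved.
#'
#' @param path Path to a delimited text file with header columns
#'   `colony_id, donor_id, receiver_id, start_time_s, duration_s`.
#' @param sep Field delimiter (default comma).
#' @return A data frame with columns `colony_id`, `donor_id`, `receiver_id`,
#'   `start_time`, `duration`.
#' @seealso [write_event_log()], [filter_short_events()]
#' @export
read_event_log <- function(path, sep = ",") {
  raw <- .read_delim_checked(path, EVENT_COLS, sep, "event log")
  events <- data.frame(
    colony_id   = raw[["colony_id"]],
    donor_id    = raw[["donor_id"]],
    receiver_id = raw[["receiver_id"]],
    start_time  = .num_col(raw[["start_time_s"]], "start_time_s", path, nonneg = TRUE),
    duration    = .num_col(raw[["duration_s"]], "duration_s", path, positive = TRUE),
    stringsAsFactors = FALSE
  )
  self <- which(events$donor_id == events$receiver_id)
  if (length(self) > 0)
    stop("donor and receiver are the same individual in ", path,
         " at line(s) ", .lines(self), call. = FALSE)
  events
}

#' Write a trophallaxis event log
#'
#' Inverse of [read_event_log()]: writes the five-column delimited format with
#' a header, preserving row order.
#'
#' @param events Event data frame as returned by [read_event_log()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_event_log <- function(events, path, sep = ",") {
  out <- data.frame(colony_id = events$colony_id, donor_id = events$donor_id,
                    receiver_id = events$receiver_id,
                    start_time_s = events$start_time, duration_s = events$duration)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an individual roster
#'
#' One row per individually marked bee: id, age in days (blank or `NA` for
#' unknown, e.g. the queen or unmarked drifters) and role (`queen`/`worker`).
#' At most one queen is allowed per colony.
#'
#' @param path Path to a delimited file with columns `colony_id, id, age_days, role`.
#' @param sep Field delimiter.
#' @return Data frame with columns `colony_id`, `id`, `age_days` (integer,
#'   `NA` = unknown), `role`.
#' @export
read_roster <- function(path, sep = ",") {
  raw <- .read_delim_checked(path, ROSTER_COLS, sep, "roster")
  age <- suppressWarnings(as.numeric(raw[["age_days"]]))
  bad <- which(is.na(age) & !(raw[["age_days"]] %in% c("NA", "")))
  if (length(bad) > 0)
    stop("non-numeric age_days in ", path, " at line(s) ", .lines(bad), call. = FALSE)
  role <- raw[["role"]]
  bad <- which(!role %in% c("queen", "worker"))
  if (length(bad) > 0)
    stop("role must be 'queen' or 'worker' in ", path, " at line(s) ", .lines(bad),
         call. = FALSE)
  dup <- which(duplicated(raw[["id"]]))
  if (length(dup) > 0)
    stop("duplicated id(s) in ", path, " at line(s) ", .lines(dup), call. = FALSE)
  for (cid in unique(raw[["colony_id"]])) {
    nq <- sum(role == "queen" & raw[["colony_id"]] == cid)
    if (nq > 1) stop("colony ", cid, " has ", nq, " queens in ", path, call. = FALSE)
  }
  data.frame(colony_id = raw[["colony_id"]], id = raw[["id"]],
             age_days = as.integer(round(age)), role = role,
             stringsAsFactors = FALSE)
}

#' @rdname read_roster
#' @param roster Roster data frame to write.
#' @export
write_roster <- function(roster, path, sep = ",") {
  out <- data.frame(colony_id = roster$colony_id, id = roster$id,
                    age_days = roster$age_days, role = roster$role)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hygienic-act table
#'
#' Long-format record of observed hygienic acts: one row per act with the
#' individual's id, the task (`uncap` or `remove`) and the time of the act.
#' Acts observed during the manual watch that precedes filming carry times
#' at or below zero.
#'
#' @param path Path to a delimited file with columns `colony_id, id, task, act_time_s`.
#' @param sep Field delimiter.
#' @return Data frame with columns `colony_id`, `id`, `task`, `act_time`.
#' @export
read_acts <- function(path, sep = ",") {
  raw <- .read_delim_checked(path, ACT_COLS, sep, "acts")
  bad <- which(!raw[["task"]] %in% HYGIENIC_TASKS)
  if (length(bad) > 0)
    stop("task must be one of ", paste(HYGIENIC_TASKS, collapse = "/"),
         " in ", path, " at line(s) ", .lines(bad), call. = FALSE)
  data.frame(colony_id = raw[["colony_id"]], id = raw[["id"]],
             task = raw[["task"]],
             act_time = .num_col(raw[["act_time_s"]], "act_time_s", path),
             stringsAsFactors = FALSE)
}

#' @rdname read_acts
#' @param acts Acts data frame to write.
#' @export
write_acts <- function(acts, path, sep = ",") {
  out <- data.frame(colony_id = acts$colony_id, id = acts$id,
                    task = acts$task, act_time_s = acts$act_time)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop exchanges too short to involve nectar transfer
#'
#' Very short trophallactic contacts rarely involve actual nectar transfer, so
#' exchanges under `min_duration` seconds are removed before any network is
#' built. The boundary value is kept: an exchange lasting exactly
#' `min_duration` seconds stays in.
#'
#' @param events Event data frame.
#' @param min_duration Minimum duration in seconds (default 2).
#' @return The events with `duration >= min_duration`, input order preserved.
#' @export
filter_short_events <- function(events, min_duration = 2) {
  stopifnot(is.numeric(min_duration), length(min_duration) == 1L)
  out <- events[events$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Code which individuals count as hygienic
#'
#' An individual is coded hygienic when it performed at least one hygienic act
#' (uncapping or removing dead brood), unless all of its social interactions
#' took place strictly before its earliest hygienic act -- in which case its
#' observed social behavior predates its hygienic status and it is recoded as
#' non-hygienic. Individuals with acts but no interactions keep the hygienic
#' flag (only networked nodes enter the downstream comparisons anyway).
#' Pre-filming acts carry times at or below zero, so they always precede every
#' filmed interaction and the flag sticks.
#'
#' An interaction starting exactly at the earliest act does not count as
#' "prior" (strict precedence); such ties are reported with a message.
#'
#' @param roster Roster data frame ([read_roster()]).
#' @param acts Hygienic act data frame ([read_acts()]).
#' @param events Event data frame, normally already passed through
#'   [filter_short_events()]. May be `NULL` or empty (no one is recoded).
#' @return Named logical vector over all roster ids.
#' @export
code_hygienic_status <- function(roster, acts, events = NULL) {
  unknown <- setdiff(unique(acts$id), roster$id)
  if (length(unknown) > 0)
    stop("hygienic act(s) reference id(s) absent from the roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  flag <- setNames(rep(FALSE, nrow(roster)), roster$id)
  if (nrow(acts) == 0) return(flag)
  first_act <- tapply(acts$act_time, acts$id, min)
  tied <- character(0)
  for (id in names(first_act)) {
    if (is.null(events) || nrow(events) == 0) { flag[id] <- TRUE; next }
    et <- events$start_time[events$donor_id == id | events$receiver_id == id]
    if (length(et) == 0) { flag[id] <- TRUE; next }
    if (any(et == first_act[[id]])) tied <- c(tied, id)
    flag[id] <- !all(et < first_act[[id]])
  }
  if (length(tied) > 0)
    message("interaction(s) simultaneous with the first hygienic act for id(s) ",
            paste(tied, collapse = ", "), "; counted as not prior")
  flag
}
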
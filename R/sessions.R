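#' @title Local session store
#' @description Append-only JSONL store of session-level training summaries
#'   (repetition counts, stance outcomes, reaction times, timestamps). No
#'   raw landmark data is ever persisted by session commands.
#' @name sessions
NULL

#' Construct a session summary
#'
#' @param module One of `"stance"`, `"squat"`, `"pushup"`, `"reflex"`.
#' @param started_at,ended_at Session timestamps (seconds since epoch or
#'   any non-decreasing numeric clock).
#' @param rep_count Repetitions counted (>= 0); default 0.
#' @param stance_outcomes Named integer vector of stance label counts;
#'   default empty.
#' @param reaction_times_s Numeric vector of measured reaction times.
#' @return A `session_summary` list.
#' @export
session_summary <- function(module = c("stance", "squat", "pushup", "reflex"),
                            started_at, ended_at, rep_count = 0L,
                            stance_outcomes = integer(0),
                            reaction_times_s = numeric(0)) {
  module <- match.arg(module)
  if (ended_at < started_at)
    stop("ended_at must be >= started_at", call. = FALSE)
  if (rep_count < 0) stop("rep_count must be >= 0", call. = FALSE)
  if (length(stance_outcomes) && any(stance_outcomes < 0))
    stop("stance outcome counts must be >= 0", call. = FALSE)
  structure(list(module = module, started_at = started_at,
                 ended_at = ended_at, rep_count = as.integer(rep_count),
                 stance_outcomes = as.list(stance_outcomes),
                 reaction_times_s = as.numeric(reaction_times_s)),
            class = "session_summary")
}

#' Append a session summary to a JSONL store
#'
#' @param store_path Path to the store file (created if absent).
#' @param summary A [session_summary()].
#' @return `store_path`, invisibly.
#' @export
append_session <- function(store_path, summary) {
  stopifnot(inherits(summary, "session_summary"))
  line <- jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = store_path, append = TRUE)
  invisible(store_path)
}

#' Load all session summaries from a store
#'
#' Corrupt lines are skipped with a warning rather than aborting the load.
#'
#' @param store_path Path to the JSONL store.
#' @return List of `session_summary` objects (empty list if the store does
#'   not exist).
#' @export
load_sessions <- function(store_path) {
  if (!file.exists(store_path)) return(list())
  lines <- readLines(store_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$module)) {
      warning("skipping corrupt session record at line ", i, call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <-
      session_summary(module = rec$module, started_at = rec$started_at,
                      ended_at = rec$ended_at,
                      rep_count = if (is.null(rec$rep_count)) 0L else rec$rep_count,
                      stance_outcomes = unlist(rec$stance_outcomes),
                      reaction_times_s = unlist(rec$reaction_times_s))
  }
  out
}

#' Aggregate statistics over a session store
#'
#' @param store A store path or a list of `session_summary` objects.
#' @return List with `session_count`, `max_reps` (named by exercise),
#'   `cumulative_reps` (named by exercise), `best_reaction_time_s`
#'   (`NA` if none), and `stance_outcomes` (summed label counts).
#' @export
aggregate_stats <- function(store) {
  sessions <- if (is.character(store)) load_sessions(store) else store
  exercises <- c("squat", "pushup")
  max_reps <- stats::setNames(rep(0L, 2L), exercises)
  cum_reps <- stats::setNames(rep(0L, 2L), exercises)
  stance_counts <- integer(0)
  rts <- numeric(0)
  for (s in sessions) {
    if (s$module %in% exercises) {
      max_reps[s$module] <- max(max_reps[s$module], s$rep_count)
      cum_reps[s$module] <- cum_reps[s$module] + s$rep_count
    }
    if (length(s$stance_outcomes)) {
      so <- unlist(s$stance_outcomes)
      for (lab in names(so))
        stance_counts[lab] <- (if (lab %in% names(stance_counts))
                                 stance_counts[[lab]] else 0L) + so[[lab]]
    }
    rts <- c(rts, s$reaction_times_s)
  }
  list(session_count = length(sessions),
       max_reps = max_reps, cumulative_reps = cum_reps,
       best_reaction_time_s = if (length(rts)) min(rts) else NA_real_,
       stance_outcomes = stance_counts)
}
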
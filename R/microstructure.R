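#' Read lick-event and session files
#'
#' Reads the two-file on-disk format written by [write_dataset()]:
#' `events.csv` with columns `subject_id, group, session_index, lick_time_s`
#' and `sessions.csv` with `subject_id, group, lesion_subtype, session_index,
#' consumption_ml`. One record is returned per row of `sessions.csv`;
#' sessions without event rows get empty lick trains. Event rows are sorted
#' by time within each session, so row order in the file does not matter;
#' duplicate timestamps within a session are a validation error.
#'
#' @param events_path,sessions_path file paths.
#' @return list of `lick_session` records.
#' @export
read_lick_events <- function(events_path, sessions_path) {
  if (!file.exists(events_path)) stop("events file not found: ", events_path)
  if (!file.exists(sessions_path))
    stop("sessions file not found: ", sessions_path)
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  se <- read.csv(sessions_path, stringsAsFactors = FALSE)
  need_ev <- c("subject_id", "group", "session_index", "lick_time_s")
  need_se <- c("subject_id", "group", "lesion_subtype", "session_index",
               "consumption_ml")
  if (!all(need_ev %in% names(ev)))
    stop("events.csv must have columns: ", paste(need_ev, collapse = ", "))
  if (!all(need_se %in% names(se)))
    stop("sessions.csv must have columns: ", paste(need_se, collapse = ", "))
  bad <- setdiff(unique(c(ev$group, se$group)), c("control", "mcao"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))

  ev_key <- paste(ev$subject_id, ev$session_index, sep = "\r")
  ev_split <- split(as.numeric(ev$lick_time_s), ev_key)
  lapply(seq_len(nrow(se)), function(i) {
    key <- paste(se$subject_id[i], se$session_index[i], sep = "\r")
    t <- sort(ev_split[[key]] %||% numeric(0))
    if (length(t) > 1 && any(diff(t) <= 0))
      stop("duplicate timestamps for subject ", se$subject_id[i],
           " session ", se$session_index[i])
    new_lick_session(se$subject_id[i], se$group[i], se$lesion_subtype[i],
                     se$session_index[i], t, se$consumption_ml[i],
                     integer(0), NA_integer_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a lick train into drinking clusters
#'
#' A cluster is a maximal run of licks whose successive inter-lick intervals
#' are all strictly below `pause_criterion`; an ILI >= the criterion starts a
#' new cluster. The clusters partition the licks in order.
#'
#' @param lick_times strictly increasing numeric vector of lick times (s).
#' @param pause_criterion pause criterion in seconds (> 0).
#' @return a data.frame with one row per cluster: `start_index`, `end_index`,
#'   `lick_count`, and a list-column `ilis` of within-cluster ILIs.
#' @examples
#' segment_clusters(c(0, 0.1, 0.2, 1.0, 1.1), pause_criterion = 0.5)
#' @export
segment_clusters <- function(lick_times, pause_criterion = 0.5) {
  if (pause_criterion <= 0) stop("pause_criterion must be positive")
  n <- length(lick_times)
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      lick_count = integer(0))
  empty$ilis <- list()
  if (n == 0L) return(empty)
  if (n > 1 && any(diff(lick_times) <= 0))
    stop("lick_times must be strictly increasing")
  id <- cluster_ids(lick_times, pause_criterion)
  starts <- which(c(TRUE, diff(id) == 1L))
  ends <- c(starts[-1L] - 1L, n)
  out <- data.frame(start_index = starts, end_index = ends,
                    lick_count = ends - starts + 1L)
  d <- diff(lick_times)
  out$ilis <- lapply(seq_along(starts), function(j)
    if (ends[j] > starts[j]) d[starts[j]:(ends[j] - 1L)] else numeric(0))
  out
}

# Integer cluster label per lick (fast path used by the summaries).
cluster_ids <- function(lick_times, pause_criterion) {
  n <- length(lick_times)
  if (n == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(lick_times) >= pause_criterion)))
}

#' Summarise one session into the seven microstructure measures
#'
#' The measures are: total water consumption (mL); total number of licks;
#' lick volume, defined as `1000 * consumption / total_licks` (mL per 1000
#' licks); mean licks per drinking cluster; total number of clusters; mean
#' ILI (s); and ILI variability as a percent coefficient of variation
#' (`100 * sample SD / mean`). ILI statistics use *within-cluster* ILIs only
#' (an ILI spanning a pause is a pause, not a lick cycle), after discarding
#' intervals below `artifact_floor` (spurious double contacts).
#'
#' With zero licks, only `consumption_ml` and the zero counts are defined;
#' ratio measures are `NA`. The ILI CV needs at least two retained ILIs.
#'
#' @param record a `lick_session`.
#' @param pause_criterion pause criterion, seconds. The 0.5 s default is the
#'   convention of the lick-microstructure literature; it is an assumption,
#'   not a fitted value.
#' @param artifact_floor minimum credible ILI, seconds; intervals below it
#'   are dropped from ILI statistics. Default 0.05 s.
#' @return one-row data.frame of class `microstructure_summary` with columns
#'   `consumption_ml`, `total_licks`, `lick_volume_ml_per_1000`,
#'   `licks_per_cluster`, `cluster_count`, `ili_mean_s`, `ili_cv_pct`.
#' @export
summarize_session <- function(record, pause_criterion = 0.5,
                              artifact_floor = 0.05) {
  stopifnot(inherits(record, "lick_session"))
  t <- record$lick_times
  n <- length(t)
  if (n == 0L) {
    out <- data.frame(consumption_ml = record$consumption_ml,
                      total_licks = 0L,
                      lick_volume_ml_per_1000 = NA_real_,
                      licks_per_cluster = NA_real_,
                      cluster_count = 0L,
                      ili_mean_s = NA_real_, ili_cv_pct = NA_real_)
    class(out) <- c("microstructure_summary", "data.frame")
    return(out)
  }
  id <- cluster_ids(t, pause_criterion)
  k <- id[n]
  d <- diff(t)
  within <- d[d < pause_criterion]
  within <- within[within >= artifact_floor]
  ili_mean <- if (length(within) >= 1) mean(within) else NA_real_
  ili_cv <- if (length(within) >= 2) 100 * sd(within) / mean(within)
            else NA_real_
  out <- data.frame(consumption_ml = record$consumption_ml,
                    total_licks = n,
                    lick_volume_ml_per_1000 = 1000 * record$consumption_ml / n,
                    licks_per_cluster = n / k,
                    cluster_count = k,
                    ili_mean_s = ili_mean, ili_cv_pct = ili_cv)
  class(out) <- c("microstructure_summary", "data.frame")
  out
}

measure_columns <- function() {
  c("consumption_ml", "total_licks", "lick_volume_ml_per_1000",
    "licks_per_cluster", "cluster_count", "ili_mean_s", "ili_cv_pct")
}

#' Aggregate session summaries to one value per subject
#'
#' The subject-level value of each measure is the unweighted mean across that
#' subject's sessions, skipping sessions where a measure is missing. This is
#' an averaging (not lick-pooling) convention; see the package vignette.
#'
#' @param summaries list of session summaries from [summarize_session()]
#'   (or a data.frame of stacked rows).
#' @return one-row `microstructure_summary` data.frame.
#' @export
aggregate_subject <- function(summaries) {
  if (is.data.frame(summaries)) df <- summaries
  else {
    if (length(summaries) == 0L)
      stop("aggregate_subject: no session summaries supplied")
    df <- do.call(rbind, summaries)
  }
  if (nrow(df) == 0L)
    stop("aggregate_subject: no session summaries supplied")
  out <- as.data.frame(lapply(df[measure_columns()], function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }))
  class(out) <- c("microstructure_summary", "data.frame")
  out
}

#' Per-subject microstructure table for a set of sessions
#'
#' Applies [summarize_session()] to every record and [aggregate_subject()]
#' within subject, producing the table the statistical battery consumes.
#'
#' @param records list of `lick_session` (from [read_lick_events()] or
#'   [simulate_cohort()]`$sessions`).
#' @inheritParams summarize_session
#' @return data.frame with `subject_id`, `group`, `lesion_subtype`, and the
#'   seven measure columns, one row per subject.
#' @export
summarize_cohort <- function(records, pause_criterion = 0.5,
                             artifact_floor = 0.05) {
  if (length(records) == 0L) stop("summarize_cohort: no records")
  meta <- data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    group = vapply(records, `[[`, "", "group"),
    lesion_subtype = vapply(records, `[[`, "", "lesion_subtype"),
    stringsAsFactors = FALSE)
  per_session <- do.call(rbind, lapply(records, summarize_session,
                                       pause_criterion = pause_criterion,
                                       artifact_floor = artifact_floor))
  ids <- unique(meta$subject_id)
  rows <- lapply(ids, function(sid) {
    sel <- meta$subject_id == sid
    cbind(meta[which(sel)[1L], , drop = FALSE],
          aggregate_subject(per_session[sel, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-subject summary table to CSV
#' @param summaries data.frame from [summarize_cohort()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_subject_summaries <- function(summaries, path) {
  write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
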
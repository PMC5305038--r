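#' Parameters of the clustered-licking generative model for one group
#'
#' A lick train is modelled as a renewal process at two timescales: clusters
#' of licks separated by long pauses, and within-cluster inter-lick intervals
#' (ILIs) that are short and highly stereotyped. Per session the generator
#' draws a Poisson number of clusters, a shifted-Poisson number of licks per
#' cluster, gamma-distributed within-cluster ILIs (positive support, low CV),
#' shifted-lognormal pauses with a hard minimum (`pause_min`) so that
#' ground-truth cluster boundaries are unambiguous, and lognormal per-lick
#' volumes whose sum is the session's consumption.
#'
#' Defaults are plausible values for a water-restricted adult rat in a 15-min
#' session, not estimates from any specific dataset: ~0.14 s ILI with 5% CV,
#' ~5 uL per lick, ~40 licks per cluster and ~60 clusters (~2400 licks,
#' ~12 mL). They are deliberately conservative and fully overridable.
#'
#' @param mean_volume_per_lick mean per-lick volume, microlitres.
#' @param ili_mean mean within-cluster inter-lick interval, seconds.
#' @param ili_cv coefficient of variation of within-cluster ILIs, as a
#'   fraction in (0, 1).
#' @param cluster_size_mean mean number of licks per cluster (>= 1).
#' @param pause_mean mean pause between clusters, seconds; must exceed
#'   `pause_min`.
#' @param pause_min hard minimum pause, seconds. Keep this above the pause
#'   criterion used for segmentation, otherwise generated clusters merge by
#'   construction.
#' @param clusters_per_session_mean mean number of clusters per session.
#' @param session_duration session length, seconds.
#' @param volume_cv coefficient of variation of per-lick volume.
#' @return an object of class `group_params` (a validated list).
#' @seealso [default_control_params()], [default_mcao_params()],
#'   [simulate_session()]
#' @export
group_params <- function(mean_volume_per_lick = 5,
                         ili_mean = 0.14,
                         ili_cv = 0.05,
                         cluster_size_mean = 40,
                         pause_mean = 5,
                         pause_min = 1,
                         clusters_per_session_mean = 60,
                         session_duration = 900,
                         volume_cv = 0.10) {
  p <- list(mean_volume_per_lick = mean_volume_per_lick,
            ili_mean = ili_mean, ili_cv = ili_cv,
            cluster_size_mean = cluster_size_mean,
            pause_mean = pause_mean, pause_min = pause_min,
            clusters_per_session_mean = clusters_per_session_mean,
            session_duration = session_duration,
            volume_cv = volume_cv)
  validate_group_params(p)
  structure(p, class = "group_params")
}

validate_group_params <- function(p) {
  num <- unlist(p)
  if (!all(is.finite(num))) stop("group_params: all parameters must be finite")
  pos <- c("mean_volume_per_lick", "ili_mean", "cluster_size_mean",
           "pause_mean", "pause_min", "session_duration")
  for (f in pos)
    if (p[[f]] <= 0) stop("group_params: '", f, "' must be strictly positive")
  if (p$ili_cv <= 0 || p$ili_cv >= 1)
    stop("group_params: 'ili_cv' must lie in (0, 1)")
  if (p$volume_cv <= 0 || p$volume_cv >= 1)
    stop("group_params: 'volume_cv' must lie in (0, 1)")
  if (p$cluster_size_mean < 1)
    stop("group_params: 'cluster_size_mean' must be >= 1")
  if (p$clusters_per_session_mean < 0)
    stop("group_params: 'clusters_per_session_mean' must be >= 0")
  if (p$pause_mean <= p$pause_min)
    stop("group_params: 'pause_mean' must exceed 'pause_min'")
  invisible(p)
}

#' Default control-group parameters
#' @return a `group_params` object.
#' @export
default_control_params <- function() group_params()

#' Default lesioned-group (MCAO) parameters
#'
#' Encodes the documented effect structure of focal ischaemia on drinking:
#' volume per lick reduced by 20%, more but smaller clusters (so total licks
#' rise slightly), and *unchanged* ILI mean and variability.
#' @return a `group_params` object.
#' @export
default_mcao_params <- function() {
  group_params(mean_volume_per_lick = 4,       # 20% deficit in lick volume
               cluster_size_mean = 32,
               clusters_per_session_mean = 80) # compensatory extra clusters
}

#' Study-design configuration for a simulated cohort
#'
#' Defaults mirror the study design the package emulates: 30 control and 22
#' lesioned subjects, 4 daily 15-min sessions each, timestamps quantised to
#' 0.01 s. Of the lesioned subjects, `n_striatal` carry the `"striatal"`
#' lesion-subtype label and the remainder `"striatal_cortical"` (13 + 9 by
#' default); the label is metadata only and does not alter generator
#' parameters.
#'
#' @param n_control,n_mcao subjects per group.
#' @param sessions_per_subject sessions per subject.
#' @param control_params,mcao_params `group_params` for each group.
#' @param timestamp_resolution recording resolution, seconds.
#' @param master_seed integer; all randomness derives from it.
#' @param n_striatal number of MCAO subjects labelled striatal-only;
#'   defaults to the 13:9 split of the emulated design, scaled to `n_mcao`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 30, n_mcao = 22,
                          sessions_per_subject = 4,
                          control_params = default_control_params(),
                          mcao_params = default_mcao_params(),
                          timestamp_resolution = 0.01,
                          master_seed = 1L,
                          n_striatal = NULL) {
  if (n_control <= 0 || n_mcao <= 0 || sessions_per_subject <= 0)
    stop("cohort_config: group sizes and sessions_per_subject must be positive")
  if (timestamp_resolution <= 0)
    stop("cohort_config: timestamp_resolution must be positive")
  if (is.null(n_striatal)) n_striatal <- round(n_mcao * 13 / 22)
  if (n_striatal < 0 || n_striatal > n_mcao)
    stop("cohort_config: n_striatal must lie in [0, n_mcao]")
  validate_group_params(control_params)
  validate_group_params(mcao_params)
  structure(list(n_control = as.integer(n_control),
                 n_mcao = as.integer(n_mcao),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 control_params = control_params,
                 mcao_params = mcao_params,
                 timestamp_resolution = timestamp_resolution,
                 master_seed = as.integer(master_seed),
                 n_striatal = as.integer(n_striatal)),
            class = "cohort_config")
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-(subject, session) seed, independent of iteration order.
# Linear-congruential style mix kept below 2^31.
derive_seed <- function(master_seed, subject_index, session_index = 0L) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 48271 + as.numeric(subject_index) * 65537) %% m
  s <- (s * 48271 + as.numeric(session_index) * 257 + 1) %% m
  as.integer(s)
}

# Snap times to the resolution grid and restore strict ordering by pushing
# colliding licks forward one step each (minimal forward shifts).
quantize_times <- function(times, resolution) {
  if (length(times) == 0L) return(numeric(0))
  k <- round(times / resolution)
  # enforce strictly increasing integer grid indices
  k <- cummax(k - seq_along(k)) + seq_along(k)
  round(k * resolution, 10)
}

#' Simulate one drinking session
#'
#' Draws a clustered lick train from the generative model in
#' [group_params()], quantises timestamps to `timestamp_resolution`, and
#' returns the session with its ground-truth cluster labels attached (used to
#' validate segmentation; they are never written to disk).
#'
#' @param params a `group_params` object.
#' @param seed integer seed; the same seed and parameters always yield an
#'   identical session.
#' @param timestamp_resolution recording resolution, seconds.
#' @param subject_id,group,lesion_subtype,session_index metadata carried on
#'   the record.
#' @return a `lick_session`: list with `subject_id`, `group`,
#'   `lesion_subtype`, `session_index`, `lick_times` (strictly increasing,
#'   on the resolution grid, all < `session_duration`), `consumption_ml`,
#'   and ground truth `true_cluster_id` (integer per lick) and
#'   `true_cluster_count`.
#' @export
simulate_session <- function(params, seed,
                             timestamp_resolution = 0.01,
                             subject_id = "S1", group = "control",
                             lesion_subtype = "none", session_index = 1L) {
  validate_group_params(params)
  if (timestamp_resolution <= 0) stop("timestamp_resolution must be positive")
  with_seed(seed, {
    n_clusters <- rpois(1L, params$clusters_per_session_mean)
    if (n_clusters == 0L) {
      return(new_lick_session(subject_id, group, lesion_subtype, session_index,
                              numeric(0), 0, integer(0), 0L))
    }
    sizes <- 1L + rpois(n_clusters, params$cluster_size_mean - 1)
    total <- sum(sizes)

    # within-cluster ILIs: gamma with stated mean and CV
    shape <- 1 / params$ili_cv^2
    n_ili <- total - n_clusters
    ilis <- if (n_ili > 0)
      rgamma(n_ili, shape = shape, scale = params$ili_mean / shape)
    else numeric(0)

    # pauses: shifted lognormal, hard minimum pause_min (> pause criterion)
    mu_excess <- params$pause_mean - params$pause_min
    sdlog <- 0.5
    pauses <- params$pause_min +
      rlnorm(n_clusters, meanlog = log(mu_excess) - sdlog^2 / 2, sdlog = sdlog)

    # interleave: each cluster opens with its pause, then size-1 ILI gaps
    gaps <- numeric(total)
    first_idx <- cumsum(c(1L, sizes[-n_clusters]))
    gaps[first_idx] <- pauses
    gaps[-first_idx] <- ilis
    times <- cumsum(gaps)
    cluster_id <- rep.int(seq_len(n_clusters), sizes)

    keep <- times < params$session_duration
    times <- times[keep]
    cluster_id <- cluster_id[keep]
    times <- quantize_times(times, timestamp_resolution)

    vols <- if (length(times) > 0) {
      sdl <- sqrt(log(1 + params$volume_cv^2))
      rlnorm(length(times),
             meanlog = log(params$mean_volume_per_lick) - sdl^2 / 2,
             sdlog = sdl)
    } else numeric(0)

    new_lick_session(subject_id, group, lesion_subtype, session_index,
                     times, sum(vols) / 1000,  # uL -> mL
                     match(cluster_id, unique(cluster_id)),
                     length(unique(cluster_id)))
  })
}

new_lick_session <- function(subject_id, group, lesion_subtype, session_index,
                             lick_times, consumption_ml,
                             true_cluster_id, true_cluster_count) {
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 lesion_subtype = as.character(lesion_subtype),
                 session_index = as.integer(session_index),
                 lick_times = lick_times,
                 consumption_ml = consumption_ml,
                 true_cluster_id = as.integer(true_cluster_id),
                 true_cluster_count = as.integer(true_cluster_count)),
            class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf("<lick_session> %s/%s session %d: %d licks, %.3f mL\n",
              x$subject_id, x$group, x$session_index,
              length(x$lick_times), x$consumption_ml))
  invisible(x)
}

#' Simulate a full two-group cohort
#'
#' Generates `n_control + n_mcao` subjects, each with
#' `sessions_per_subject` sessions, using per-(subject, session) seeds
#' derived deterministically from `master_seed` so the result is independent
#' of iteration order and byte-reproducible.
#'
#' @param config a [cohort_config()].
#' @return a `lick_cohort`: list with `sessions` (list of `lick_session`)
#'   and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- data.frame(
    subject_id = c(sprintf("C%02d", seq_len(config$n_control)),
                   sprintf("M%02d", seq_len(config$n_mcao))),
    group = rep(c("control", "mcao"), c(config$n_control, config$n_mcao)),
    lesion_subtype = c(rep("none", config$n_control),
                       rep(c("striatal", "striatal_cortical"),
                           c(config$n_striatal,
                             config$n_mcao - config$n_striatal))),
    stringsAsFactors = FALSE)
  sessions <- vector("list", nrow(subjects) * config$sessions_per_subject)
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    par <- if (subjects$group[i] == "control") config$control_params
           else config$mcao_params
    for (s in seq_len(config$sessions_per_subject)) {
      k <- k + 1L
      sessions[[k]] <- simulate_session(
        par, seed = derive_seed(config$master_seed, i, s),
        timestamp_resolution = config$timestamp_resolution,
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        lesion_subtype = subjects$lesion_subtype[i], session_index = s)
    }
  }
  structure(list(sessions = sessions, config = config), class = "lick_cohort")
}

#' @export
print.lick_cohort <- function(x, ...) {
  cat(sprintf("<lick_cohort> %d sessions, %d control + %d mcao subjects\n",
              length(x$sessions), x$config$n_control, x$config$n_mcao))
  invisible(x)
}

#' Write a cohort to the on-disk event/consumption format
#'
#' Produces `events.csv` (`subject_id, group, session_index, lick_time_s`,
#' one row per lick, timestamps fixed-point at the recording resolution) and
#' `sessions.csv` (`subject_id, group, lesion_subtype, session_index,
#' consumption_ml`). Timestamps are validated to be strictly increasing and
#' on the resolution grid before anything is written.
#'
#' @param cohort a `lick_cohort` (or plain list of `lick_session`).
#' @param directory output directory, created if needed.
#' @param timestamp_resolution resolution used for fixed-point formatting and
#'   validation; defaults to the cohort's configured value.
#' @return invisibly, the paths of the two files written.
#' @export
write_dataset <- function(cohort, directory, timestamp_resolution = NULL) {
  sessions <- if (inherits(cohort, "lick_cohort")) cohort$sessions else cohort
  if (length(sessions) == 0L) stop("write_dataset: empty dataset")
  if (is.null(timestamp_resolution))
    timestamp_resolution <- if (inherits(cohort, "lick_cohort"))
      cohort$config$timestamp_resolution else 0.01
  digits <- max(0L, ceiling(-log10(timestamp_resolution)))

  for (s in sessions) {
    t <- s$lick_times
    if (length(t) > 1 && any(diff(t) <= 0))
      stop("write_dataset: non-increasing timestamps in subject ",
           s$subject_id, " session ", s$session_index)
    if (length(t) > 0 &&
        any(abs(t / timestamp_resolution -
                round(t / timestamp_resolution)) > 1e-6))
      stop("write_dataset: timestamps of subject ", s$subject_id,
           " session ", s$session_index,
           " are not on the ", timestamp_resolution, " s grid")
  }

  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  events_path <- file.path(directory, "events.csv")
  sessions_path <- file.path(directory, "sessions.csv")

  ev <- do.call(rbind, lapply(sessions, function(s) {
    if (length(s$lick_times) == 0L) return(NULL)
    data.frame(subject_id = s$subject_id, group = s$group,
               session_index = s$session_index,
               lick_time_s = sprintf(paste0("%.", digits, "f"), s$lick_times),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(subject_id = character(0), group = character(0),
                     session_index = integer(0), lick_time_s = character(0))
  se <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               lesion_subtype = s$lesion_subtype,
               session_index = s$session_index,
               consumption_ml = s$consumption_ml, stringsAsFactors = FALSE)))
  write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  write.csv(se, sessions_path, row.names = FALSE, quote = FALSE)
  invisible(c(events = events_path, sessions = sessions_path))
}
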
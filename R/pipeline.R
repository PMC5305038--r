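#' Build a pipeline run configuration
#'
#' Collects every tunable of the simulate -> summarize -> compare pipeline in
#' one validated object. Either give `events_path`/`sessions_path` to analyse
#' recorded data, or leave them `NULL` to analyse a cohort simulated from
#' `cohort` (a [cohort_config()]).
#'
#' @param events_path,sessions_path input CSVs, or `NULL` to simulate.
#' @param cohort a [cohort_config()] used when simulating.
#' @param pause_criterion,artifact_floor segmentation parameters (s).
#' @param alpha,family Bonferroni settings for the battery.
#' @param rscale JZS prior scale.
#' @param assignment per-measure test assignment
#'   ([default_test_assignment()]).
#' @param master_seed seed forwarded to the simulator (overrides the one in
#'   `cohort` when given).
#' @return a `run_config` list.
#' @export
run_config <- function(events_path = NULL, sessions_path = NULL,
                       cohort = cohort_config(),
                       pause_criterion = 0.5, artifact_floor = 0.05,
                       alpha = 0.05, family = 7, rscale = 1,
                       assignment = default_test_assignment(),
                       master_seed = NULL) {
  if (xor(is.null(events_path), is.null(sessions_path)))
    stop("run_config: give both events_path and sessions_path, or neither")
  if (pause_criterion <= 0) stop("run_config: pause_criterion must be > 0")
  if (artifact_floor < 0) stop("run_config: artifact_floor must be >= 0")
  if (artifact_floor >= pause_criterion)
    stop("run_config: artifact_floor must be below pause_criterion")
  if (family < length(assignment))
    stop("run_config: family size below number of measures")
  if (!all(assignment %in% c("t", "u")))
    stop("run_config: assignment values must be 't' or 'u'")
  if (!is.null(master_seed)) {
    cohort$master_seed <- as.integer(master_seed)
  }
  structure(list(events_path = events_path, sessions_path = sessions_path,
                 cohort = cohort, pause_criterion = pause_criterion,
                 artifact_floor = artifact_floor, alpha = alpha,
                 family = family, rscale = rscale, assignment = assignment),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Flat JSON mirroring the [run_config()] arguments; `cohort`,
#' `control_params` and `mcao_params` may be nested objects overriding the
#' corresponding defaults.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(l, nm, def) if (!is.null(l[[nm]])) l[[nm]] else def
  gp <- function(over, base) {
    if (is.null(over)) return(base)
    do.call(group_params, utils::modifyList(unclass(base), as.list(over)))
  }
  co <- raw$cohort %||% list()
  cohort <- cohort_config(
    n_control = take(co, "n_control", 30),
    n_mcao = take(co, "n_mcao", 22),
    sessions_per_subject = take(co, "sessions_per_subject", 4),
    control_params = gp(co$control_params, default_control_params()),
    mcao_params = gp(co$mcao_params, default_mcao_params()),
    timestamp_resolution = take(co, "timestamp_resolution", 0.01),
    master_seed = take(co, "master_seed", 1L),
    n_striatal = co$n_striatal)
  run_config(events_path = raw$events_path, sessions_path = raw$sessions_path,
             cohort = cohort,
             pause_criterion = take(raw, "pause_criterion", 0.5),
             artifact_floor = take(raw, "artifact_floor", 0.05),
             alpha = take(raw, "alpha", 0.05),
             family = take(raw, "family", 7),
             rscale = take(raw, "rscale", 1),
             assignment = unlist(take(raw, "assignment",
                                      default_test_assignment())),
             master_seed = raw$master_seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Small stable content hash (FNV-1a, 32-bit) for provenance blocks.
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 2166136261
  for (b in s) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full analysis pipeline
#'
#' Orchestrates data acquisition (read or simulate), per-subject
#' summarisation, the seven-measure two-group battery with Bonferroni and
#' Bayes factors, a lesion-subtype one-way ANOVA on lick volume and
#' consumption, within-lesion correlations (lick volume against total licks,
#' plus any covariate supplied), and a per-group coefficient-of-variation
#' table. Deterministic given the configuration; every defaulted assumption
#' (pause criterion, artifact floor, rscale) is recorded in the report's
#' `assumptions` block.
#'
#' @param config a [run_config()].
#' @param covariate optional named list: `name` plus a data.frame with
#'   `subject_id` and `value`, correlated against lick volume within the
#'   lesioned group (e.g. an atrophy measure).
#' @param out_dir if non-`NULL`, writes `subject_summaries.csv`,
#'   `report.json` and `report.csv` there; partial outputs are removed if a
#'   later stage fails.
#' @return the report bundle (a `lick_report` list).
#' @export
run_analysis <- function(config, covariate = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  records <- stage("acquire", {
    if (!is.null(config$events_path))
      read_lick_events(config$events_path, config$sessions_path)
    else
      simulate_cohort(config$cohort)$sessions
  })

  summaries <- stage("summarize",
    summarize_cohort(records, pause_criterion = config$pause_criterion,
                     artifact_floor = config$artifact_floor))

  battery <- stage("compare",
    compare_groups(summaries, assignment = config$assignment,
                   alpha = config$alpha, family = config$family,
                   rscale = config$rscale))

  subtype_anova <- stage("subtype_anova", {
    st <- ifelse(summaries$group == "control", "control",
                 summaries$lesion_subtype)
    lapply(c("lick_volume_ml_per_1000", "consumption_ml"), function(msr) {
      g <- split(summaries[[msr]], st)
      g <- g[order(names(g) != "control")]   # control first
      if (length(g) < 2 || any(vapply(g, length, 1L) < 2)) return(NULL)
      one_way_anova(g, measure = msr)
    }) |> stats::setNames(c("lick_volume_ml_per_1000", "consumption_ml"))
  })

  correlations <- stage("correlate", {
    mc <- summaries[summaries$group == "mcao", , drop = FALSE]
    out <- list()
    if (nrow(mc) >= 3)
      out$lick_volume_vs_total_licks <-
        pearson_r(mc$lick_volume_ml_per_1000, mc$total_licks,
                  measure = "lick_volume_vs_total_licks")
    if (!is.null(covariate)) {
      m <- merge(mc, covariate$data, by = "subject_id")
      if (nrow(m) >= 3)
        out[[paste0("lick_volume_vs_", covariate$name)]] <-
          pearson_r(m$lick_volume_ml_per_1000, m$value,
                    measure = paste0("lick_volume_vs_", covariate$name))
    }
    out
  })

  cv_table <- stage("cv_table", {
    do.call(rbind, lapply(split(summaries, summaries$group), function(d) {
      vals <- vapply(measure_columns(), function(msr) {
        x <- d[[msr]][!is.na(d[[msr]])]
        if (length(x) >= 2 && mean(x) != 0) coefficient_of_variation(x)
        else NA_real_
      }, 1)
      data.frame(group = d$group[1], measure = measure_columns(),
                 cv_pct = vals, row.names = NULL, stringsAsFactors = FALSE)
    }))
  })

  bundle <- structure(list(
    summaries = summaries, battery = battery,
    subtype_anova = subtype_anova, correlations = correlations,
    cv_table = cv_table,
    assumptions = list(pause_criterion_s = config$pause_criterion,
                       artifact_floor_s = config$artifact_floor,
                       rscale = config$rscale, alpha = config$alpha,
                       family = config$family,
                       subject_aggregation = "mean over sessions"),
    provenance = list(package = "lickstat",
                      version = as.character(packageVersion("lickstat")),
                      config_hash = config_hash(config),
                      r_version = R.version.string)),
    class = "lick_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    written <- character(0)
    tryCatch({
      p <- file.path(out_dir, "subject_summaries.csv")
      write_subject_summaries(summaries, p); written <- c(written, p)
      p <- file.path(out_dir, "report.csv")
      write.csv(render_report(bundle), p, row.names = FALSE)
      written <- c(written, p)
      p <- file.path(out_dir, "report.json")
      jsonlite::write_json(
        list(battery = battery, cv_table = cv_table,
             assumptions = bundle$assumptions,
             provenance = bundle$provenance),
        p, auto_unbox = TRUE, digits = NA, na = "null")
      written <- c(written, p)
    }, error = function(e) {
      unlink(written)
      stop("pipeline stage 'write': ", conditionMessage(e), call. = FALSE)
    })
  }
  bundle
}

#' Render a report bundle as a per-measure table
#'
#' One row per measure in the battery, in stable column order:
#' measure, test, statistic, df, p, Bonferroni-corrected alpha and verdict,
#' and the reported Bayes factor `K` (BF01 when the null is favoured,
#' BF10 otherwise) with its direction.
#'
#' @param bundle a `lick_report` from [run_analysis()] (or a bare battery
#'   data.frame).
#' @return data.frame ready for printing or CSV export.
#' @export
render_report <- function(bundle) {
  battery <- if (inherits(bundle, "lick_report")) bundle$battery else bundle
  cols <- c("measure", "test", "statistic", "df1", "df2", "p",
            "bonferroni_alpha", "significant", "K", "bf_direction")
  if (nrow(battery) == 0L)
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  battery[, cols]
}

#' @export
print.lick_report <- function(x, ...) {
  cat("<lick_report>\n")
  print(render_report(x), digits = 4)
  invisible(x)
}
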
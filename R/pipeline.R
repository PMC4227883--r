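# End-to-end pipeline drivers binding simulation, scoring, metrics and
# group statistics, with file output and a JSON run report. These are the
# programmatic equivalents of the command-line subcommands in
# inst/scripts/spinegap.

#' Simulate a cohort and write it to disk
#'
#' Dispatches to the synthetic-data generators and writes the tidy data
#' files plus a parameter/seed sidecar. `kind = "spines"` writes a
#' presence table, `"boutons"` a ratio series, `"gapcross"` a trial log.
#'
#' @param out_dir Output directory (must exist).
#' @param kind `"spines"`, `"boutons"` or `"gapcross"`.
#' @param params A matching parameter object ([spine_kinetics_params()],
#'   [bouton_kinetics_params()] or [agent_params()]); defaults per kind.
#' @param session_cfg,sampler Gap-cross configuration (ignored otherwise).
#' @param seed Optional seed overriding the one in `params`.
#' @return The written data file path, invisibly.
#' @export
run_simulate <- function(out_dir, kind = c("spines", "boutons", "gapcross"),
                         params = NULL, session_cfg = session_config(),
                         sampler = sampler_params(), seed = NULL) {
  kind <- match.arg(kind)
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  if (kind == "spines") {
    if (is.null(params)) params <- spine_kinetics_params()
    if (!is.null(seed)) params$seed <- chk_count(seed, "seed", 0L)
    pm <- simulate_spine_cohort(params)
    path <- file.path(out_dir, "spine_presence.csv")
    write_presence(pm, path, params = params, seed = params$seed)
  } else if (kind == "boutons") {
    if (is.null(params)) params <- bouton_kinetics_params()
    if (!is.null(seed)) params$seed <- chk_count(seed, "seed", 0L)
    bs <- simulate_bouton_series(params)
    path <- file.path(out_dir, "bouton_ratios.csv")
    write_bouton_series(bs, path, params = params, seed = params$seed)
  } else {
    if (is.null(params))
      params <- agent_params(midpoint_cm_by_session =
                               seq(4.8, 5.4, length.out = 8))
    if (!is.null(seed)) params$seed <- chk_count(seed, "seed", 0L)
    trials <- simulate_gap_agent(params, session_cfg, sampler)
    path <- file.path(out_dir, "gap_trials.csv")
    write_trials(trials, path, params = params, seed = params$seed)
  }
  invisible(path)
}

#' Dynamics metrics and group comparison in one invocation
#'
#' Runs the full spine/bouton analysis chain on a presence matrix (or a
#' tidy presence file): per-interval dynamics, survival curve, newborn
#' fates where the session grid allows, per-animal aggregation, and -- when
#' a two-level `groups` mapping is given -- Mann-Whitney comparisons of
#' per-animal turnover, gain and loss fractions. Tables and a JSON run
#' report are written when `out_dir` is supplied.
#'
#' @param presence A `presence_matrix`, tidy records data frame, or a path
#'   to a tidy presence CSV.
#' @param groups Optional named character vector mapping `animal_id` to
#'   group label (exactly two levels for the comparisons).
#' @param out_dir Optional output directory for the result tables.
#' @param baseline_day Baseline session for the survival curve.
#' @param birth_day Newborn cohort day for fate classification; `NULL`
#'   (default) uses the second session when at least two later sessions
#'   exist, else skips fates.
#' @param turnover_formula Passed to [interval_dynamics()].
#' @return List with `intervals`, `survival`, `fates` (possibly `NULL`),
#'   `per_animal`, `comparisons` (possibly `NULL`) and `report`.
#' @export
run_dynamics <- function(presence, groups = NULL, out_dir = NULL,
                         baseline_day = 0, birth_day = NULL,
                         turnover_formula = c("flanking", "baseline")) {
  turnover_formula <- match.arg(turnover_formula)
  pm <- if (inherits(presence, "presence_matrix")) presence
        else if (is.character(presence)) read_presence(presence)
        else build_presence_matrix(presence)
  if (n_structures(pm) == 0L)
    stop("empty input: no structures to analyze", call. = FALSE)
  if (all(is.na(pm$calls))) {
    warning("all cells are censored; metrics are empty", call. = FALSE)
    return(list(intervals = NULL, survival = NULL, fates = NULL,
                per_animal = NULL, comparisons = NULL,
                report = list(n_structures = n_structures(pm),
                              all_censored = TRUE)))
  }
  ints <- interval_dynamics(pm, turnover_formula = turnover_formula)
  surv <- survival_fraction(pm, baseline_day = baseline_day)
  days <- session_days(pm)
  if (is.null(birth_day) && length(days) >= 4L) birth_day <- days[2]
  fates <- NULL
  if (!is.null(birth_day)) {
    j <- match(birth_day, days)
    if (!is.na(j) && j + 2L <= length(days))
      fates <- classify_new_structure_fates(
        pm, birth_day = birth_day, horizon_days = days[c(j + 1L, j + 2L)])
  }
  per_animal <- aggregate_by_animal(ints, survival = surv, fates = fates)
  comparisons <- NULL
  if (!is.null(groups)) {
    g <- groups[per_animal$animal_id]
    if (anyNA(g))
      stop("`groups` lacks a label for animal(s): ",
           paste(per_animal$animal_id[is.na(g)], collapse = ", "),
           call. = FALSE)
    metrics <- intersect(c("turnover_ratio", "frac_gained", "frac_lost",
                           "survival", "frac_transient", "frac_persistent"),
                         names(per_animal))
    comparisons <- do.call(rbind, lapply(metrics, function(m) {
      v <- per_animal[[m]]
      ok <- !is.na(v)
      gc <- group_compare(v[ok], g[ok])
      data.frame(metric = m,
                 group_a = gc$summary$group[1],
                 mean_a = gc$summary$mean[1], sem_a = gc$summary$sem[1],
                 group_b = gc$summary$group[2],
                 mean_b = gc$summary$mean[2], sem_b = gc$summary$sem[2],
                 u = gc$test$u, p_value = gc$test$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  report <- list(
    n_structures = n_structures(pm),
    session_days = days,
    turnover_formula = turnover_formula,
    baseline_day = baseline_day,
    birth_day = birth_day,
    n_censored_cells = sum(is.na(pm$calls)),
    package_version = as.character(utils::packageVersion("spinegap")))
  out <- list(intervals = ints, survival = surv, fates = fates,
              per_animal = per_animal, comparisons = comparisons,
              report = report)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      stop("output directory does not exist: ", out_dir, call. = FALSE)
    utils::write.csv(ints, file.path(out_dir, "interval_dynamics.csv"),
                     row.names = FALSE)
    utils::write.csv(surv, file.path(out_dir, "survival.csv"),
                     row.names = FALSE)
    if (!is.null(fates))
      utils::write.csv(fates, file.path(out_dir, "fates.csv"),
                       row.names = FALSE)
    utils::write.csv(per_animal, file.path(out_dir, "per_animal.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons,
                       file.path(out_dir, "group_comparisons.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Gap-cross summary statistics from trial logs
#'
#' Computes the per-distance success-rate table and the early/late
#' improvement table from gap-cross trials (one or many animals), writing
#' them alongside a run report when `out_dir` is given.
#'
#' @param trials A `gap_trials` data frame or path to a trial-log CSV.
#' @param out_dir Optional output directory.
#' @param early_sessions,late_sessions Session windows for [improvement()].
#' @return List with `by_distance`, `improvement` and `report`.
#' @export
run_gapcross <- function(trials, out_dir = NULL, early_sessions = 1:4,
                         late_sessions = 5:8) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (nrow(trials) == 0L)
    stop("empty input: no trials to analyze", call. = FALSE)
  by_distance <- success_rate_by_distance(trials)
  imp <- tryCatch(improvement(trials, early_sessions, late_sessions),
                  error = function(e) NULL)
  report <- list(
    n_trials = nrow(trials),
    n_sessions = length(unique(trials$session)),
    n_success = sum(trials$outcome == "success"),
    n_incomplete = sum(trials$outcome == "incomplete"),
    package_version = as.character(utils::packageVersion("spinegap")))
  out <- list(by_distance = by_distance, improvement = imp,
              report = report)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      stop("output directory does not exist: ", out_dir, call. = FALSE)
    utils::write.csv(by_distance,
                     file.path(out_dir, "success_by_distance.csv"),
                     row.names = FALSE)
    if (!is.null(imp)) {
      utils::write.csv(imp$per_animal,
                       file.path(out_dir, "improvement_per_animal.csv"),
                       row.names = FALSE)
      utils::write.csv(imp$mean,
                       file.path(out_dir, "improvement_mean.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
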
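# Dynamics metrics computed from a presence matrix: per-interval turnover
# and gain/loss fractions, survival curves, newborn fate classes, and
# per-animal aggregation. The core is kind-agnostic: spine and bouton
# matrices run through identical code.

#' Per-interval gain, loss and turnover
#'
#' For every animal and every pair of consecutive imaging sessions,
#' counts structures lost (present at `t`, absent at `t + delta`) and
#' gained (absent or unborn at `t`, present at `t + delta`) and derives
#'
#' * `frac_lost  = n_lost   / n_prev`
#' * `frac_gained = n_gained / n_prev`
#' * `turnover_ratio = (n_gained + n_lost) / (n_prev + n_curr)`
#'   (the `"flanking"` formula, standard in the chronic-imaging
#'   literature; equal to the mean of the gain and loss fractions when
#'   counts are stable), or
#'   `(n_gained + n_lost) / (2 * n_prev)` with
#'   `turnover_formula = "baseline"`.
#'
#' Cells censored at either flank of an interval drop out of both the
#' numerator and denominator for that interval. The conservation identity
#' `n_curr = n_prev - n_lost + n_gained` holds for every row.
#'
#' @param pm A `presence_matrix`.
#' @param turnover_formula `"flanking"` (default) or `"baseline"`.
#' @return Data frame (class `interval_dynamics`): one row per animal x
#'   interval with counts and fractions; the formula choice is recorded in
#'   the `"turnover_formula"` attribute.
#' @examples
#' pm <- simulate_spine_cohort(spine_kinetics_params(
#'   n_animals = 2, n_initial_per_animal = 100, seed = 1))
#' interval_dynamics(pm)
#' @export
interval_dynamics <- function(pm,
                              turnover_formula = c("flanking", "baseline")) {
  stopifnot(inherits(pm, "presence_matrix"))
  turnover_formula <- match.arg(turnover_formula)
  if (length(pm$days) < 2L)
    stop("at least two imaging sessions are required", call. = FALSE)
  animals <- unique(pm$structures$animal_id)
  rows <- list()
  for (a in animals) {
    calls <- pm$calls[pm$structures$animal_id == a, , drop = FALSE]
    for (j in seq_len(length(pm$days) - 1L)) {
      ok <- !is.na(calls[, j]) & !is.na(calls[, j + 1L])
      prev <- calls[ok, j] == 1L
      curr <- calls[ok, j + 1L] == 1L
      n_prev <- sum(prev); n_curr <- sum(curr)
      n_lost <- sum(prev & !curr); n_gained <- sum(!prev & curr)
      denom <- if (turnover_formula == "flanking") n_prev + n_curr
               else 2 * n_prev
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = a, interval_start = pm$days[j],
        interval_end = pm$days[j + 1L],
        n_prev = n_prev, n_curr = n_curr,
        n_gained = n_gained, n_lost = n_lost,
        turnover_ratio = if (denom > 0) (n_gained + n_lost) / denom
                         else NA_real_,
        frac_gained = if (n_prev > 0) n_gained / n_prev else NA_real_,
        frac_lost = if (n_prev > 0) n_lost / n_prev else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "turnover_formula") <- turnover_formula
  class(out) <- c("interval_dynamics", "data.frame")
  out
}

#' Survival fraction of structures present at a baseline session
#'
#' Fraction of structures present at the baseline session that are still
#' present at each later session. Because presence is contiguous
#' (no-resurrection, enforced when the matrix is built), "still present at
#' offset k" means continuously present through offset k. Returns one
#' curve per animal plus the pooled curve; each curve equals 1 at offset 0
#' and is non-increasing. Structures censored at a given session drop out
#' of that session's numerator and denominator.
#'
#' @param pm A `presence_matrix`.
#' @param baseline_day Session day to anchor the cohort (default 0).
#' @return Data frame (class `survival_curve`): `animal_id` (including
#'   `"pooled"`), `offset_day`, `n_at_risk`, `n_surviving`, `fraction`.
#' @examples
#' pm <- simulate_spine_cohort(spine_kinetics_params(
#'   n_animals = 2, n_initial_per_animal = 100, seed = 1))
#' subset(survival_fraction(pm), animal_id == "pooled")
#' @export
survival_fraction <- function(pm, baseline_day = 0) {
  stopifnot(inherits(pm, "presence_matrix"))
  b <- match(baseline_day, pm$days)
  if (is.na(b))
    stop("baseline day ", baseline_day, " is not an imaging session",
         call. = FALSE)
  groups <- c(stats::setNames(as.list(unique(pm$structures$animal_id)),
                              unique(pm$structures$animal_id)),
              list(pooled = unique(pm$structures$animal_id)))
  rows <- list()
  for (g in names(groups)) {
    calls <- pm$calls[pm$structures$animal_id %in% groups[[g]], ,
                      drop = FALSE]
    base <- !is.na(calls[, b]) & calls[, b] == 1L
    for (j in b:length(pm$days)) {
      obs <- base & !is.na(calls[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = g, offset_day = pm$days[j] - pm$days[b],
        n_at_risk = sum(obs),
        n_surviving = sum(obs & calls[, j] == 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fraction <- ifelse(out$n_at_risk > 0,
                         out$n_surviving / out$n_at_risk, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fate classes of newly formed structures
#'
#' Structures that first appear at `birth_day` are tracked over the two
#' following imaging sessions and classified as *transient* (already absent
#' at the first horizon, i.e. surviving less than one interval), *mid*
#' (present at the first horizon but absent at the second), or *persistent*
#' (still present at the second horizon). Fractions are over the
#' classifiable newborn cohort; structures censored at a deciding session
#' are excluded.
#'
#' @param pm A `presence_matrix`.
#' @param birth_day Session day at which the cohort first appeared.
#' @param horizon_days The two later session days used for classification.
#' @return Data frame (class `fate_classification`): per animal and pooled,
#'   cohort and classifiable counts, and `n_`/`frac_` for each of
#'   `transient`, `mid`, `persistent`.
#' @export
classify_new_structure_fates <- function(pm, birth_day = 4,
                                         horizon_days = c(8, 12)) {
  stopifnot(inherits(pm, "presence_matrix"),
            length(horizon_days) == 2L)
  h <- match(horizon_days, pm$days)
  if (anyNA(h) || is.na(match(birth_day, pm$days)))
    stop("birth day and both horizon days must be imaging sessions",
         call. = FALSE)
  cohort <- which(!is.na(pm$structures$birth_day) &
                  pm$structures$birth_day == birth_day)
  animals <- unique(pm$structures$animal_id)
  tally <- function(idx) {
    h1 <- pm$calls[idx, h[1]]
    h2 <- pm$calls[idx, h[2]]
    transient <- !is.na(h1) & h1 == 0L
    mid <- !is.na(h1) & h1 == 1L & !is.na(h2) & h2 == 0L
    persistent <- !is.na(h2) & h2 == 1L
    classifiable <- transient | mid | persistent
    c(n_cohort = length(idx), n_classifiable = sum(classifiable),
      n_transient = sum(transient), n_mid = sum(mid),
      n_persistent = sum(persistent))
  }
  rows <- lapply(c(as.list(animals), list(animals)), function(g) {
    idx <- cohort[pm$structures$animal_id[cohort] %in% g]
    tally(idx)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(animal_id = c(animals, "pooled"),
                          stringsAsFactors = FALSE), out)
  for (cls in c("transient", "mid", "persistent"))
    out[[paste0("frac_", cls)]] <-
      ifelse(out$n_classifiable > 0,
             out[[paste0("n_", cls)]] / out$n_classifiable, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("fate_classification", "data.frame")
  out
}

#' Aggregate interval dynamics to one row per animal
#'
#' The animal is the unit of statistical analysis: structures from all
#' fields of an animal are pooled into the per-interval counts (a
#' structure-weighted mean across fields), and here the per-interval
#' fractions are averaged across intervals into a single value per animal.
#' Optionally merges each animal's survival fraction at the largest offset
#' and its newborn fate fractions.
#'
#' @param intervals An [interval_dynamics()] table.
#' @param survival Optional [survival_fraction()] table.
#' @param fates Optional [classify_new_structure_fates()] table.
#' @return Data frame with one row per animal: mean `turnover_ratio`,
#'   `frac_gained`, `frac_lost` (plus `survival`, `frac_transient`,
#'   `frac_mid`, `frac_persistent` when supplied).
#' @export
aggregate_by_animal <- function(intervals, survival = NULL, fates = NULL) {
  stopifnot(inherits(intervals, "data.frame"))
  agg <- stats::aggregate(
    intervals[c("turnover_ratio", "frac_gained", "frac_lost")],
    by = list(animal_id = intervals$animal_id),
    FUN = mean, na.rm = TRUE)
  if (!is.null(survival)) {
    sv <- survival[survival$animal_id != "pooled", , drop = FALSE]
    last <- max(sv$offset_day)
    sv <- sv[sv$offset_day == last, c("animal_id", "fraction")]
    names(sv)[2] <- "survival"
    agg <- merge(agg, sv, by = "animal_id", all.x = TRUE)
  }
  if (!is.null(fates)) {
    ft <- fates[fates$animal_id != "pooled",
                c("animal_id", "frac_transient", "frac_mid",
                  "frac_persistent")]
    agg <- merge(agg, ft, by = "animal_id", all.x = TRUE)
  }
  agg[order(agg$animal_id), , drop = FALSE]
}

#' Mean, SEM and n of a per-animal metric by group
#'
#' @param values Numeric per-animal values.
#' @param group Group label per animal.
#' @return Data frame with `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, group) {
  stopifnot(length(values) == length(group))
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    v <- v[!is.na(v)]
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
        `rownames<-`(out, NULL))
}
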
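# Converting raw longitudinal annotations into presence matrices: the
# brightness-threshold hysteresis rule for boutons and the dual-scorer
# reconciliation protocol.

#' Hysteresis classification of a bouton brightness-ratio series
#'
#' Applies the two-threshold scoring rule for axonal boutons: a bouton is
#' scored as new (present) when its brightness reaches `appear_threshold`
#' times the surrounding axon (3.0x by default) and as lost when its
#' brightness falls below `persist_threshold` times the axon (1.3x).
#' Ratios between the two thresholds preserve the previous state
#' (hysteresis): a faded-but-not-lost bouton stays present, a dim position
#' that never reached 3.0x stays absent. At the first session a bouton is
#' present iff its ratio meets the appearance threshold -- in particular, a
#' first-session ratio inside the hysteresis band scores absent.
#'
#' @param ratios Numeric vector of per-session brightness ratios (> 0;
#'   `NA` = censored session, state carries across it).
#' @param appear_threshold Appearance ("new bouton") threshold.
#' @param persist_threshold Retention threshold; must be below
#'   `appear_threshold`.
#' @return Integer vector of presence calls (1/0, `NA` where censored).
#' @examples
#' classify_bouton_series(c(4.0, 2.0, 1.0, 4.0))  # 1 1 0 1
#' classify_bouton_series(c(2.0, 2.0, 2.0))       # 0 0 0
#' @export
classify_bouton_series <- function(ratios, appear_threshold = 3.0,
                                   persist_threshold = 1.3) {
  if (!is.numeric(ratios))
    stop("`ratios` must be numeric", call. = FALSE)
  if (persist_threshold >= appear_threshold)
    stop("`persist_threshold` must be below `appear_threshold`",
         call. = FALSE)
  if (any(!is.na(ratios) & ratios <= 0))
    stop("brightness ratios must be positive", call. = FALSE)
  state <- FALSE
  out <- integer(length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    if (is.na(r)) {
      out[i] <- NA_integer_
      next
    }
    state <- if (state) r >= persist_threshold else r >= appear_threshold
    out[i] <- as.integer(state)
  }
  out
}

#' Score a table of bouton ratio series into a presence matrix
#'
#' Applies [classify_bouton_series()] to every bouton of a tidy ratio table
#' (as produced by [simulate_bouton_series()] or read from disk) and
#' assembles the resulting calls into a `presence_matrix`. Because
#' classification noise can make a bouton appear, vanish and "reappear",
#' the matrix is built under the usual no-resurrection policy.
#'
#' @param series A data frame with `animal_id`, `field_id`, `structure_id`,
#'   `session_day`, `ratio`.
#' @inheritParams classify_bouton_series
#' @inheritParams build_presence_matrix
#' @return A `presence_matrix` of bouton calls.
#' @export
classify_bouton_table <- function(series, appear_threshold = 3.0,
                                  persist_threshold = 1.3,
                                  policy = c("split", "strict")) {
  policy <- match.arg(policy)
  series <- as.data.frame(series)
  need <- c("structure_id", "session_day", "ratio")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("`series` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(series$animal_id)) series$animal_id <- "a1"
  if (is.null(series$field_id)) series$field_id <- "f1"
  key <- paste(series$animal_id, series$field_id, series$structure_id,
               sep = "\r")
  ord <- order(key, series$session_day)
  series <- series[ord, ]
  key <- key[ord]
  series$present <- unlist(lapply(split(series$ratio, factor(key, unique(key))),
                                  classify_bouton_series,
                                  appear_threshold = appear_threshold,
                                  persist_threshold = persist_threshold),
                           use.names = FALSE)
  series$kind <- "bouton"
  build_presence_matrix(series[c("animal_id", "field_id", "structure_id",
                                 "kind", "session_day", "present")],
                        policy = policy, kind = "bouton")
}

#' Reconcile two independent scorers' presence calls
#'
#' Image series are annotated by two experimenters independently; where
#' their calls agree the call passes through, and where they disagree the
#' call of a third scorer is used when available. Disagreements with no
#' third call are censored (`NA`) and excluded from downstream counts.
#' Every disagreement is logged.
#'
#' @param calls_a,calls_b `presence_matrix` objects covering identical
#'   structures and sessions.
#' @param calls_c Optional third-scorer `presence_matrix` over the same
#'   structures x sessions.
#' @return A list with `matrix` (the reconciled `presence_matrix`, rebuilt
#'   under the split policy in case resolution broke contiguity) and
#'   `discrepancies` (data frame of `structure_id`, `session_day`,
#'   `call_a`, `call_b`, `resolution`; `resolution` is `NA` when
#'   unresolved/censored).
#' @export
reconcile_annotations <- function(calls_a, calls_b, calls_c = NULL) {
  stopifnot(inherits(calls_a, "presence_matrix"),
            inherits(calls_b, "presence_matrix"))
  align_check <- function(x, y, who) {
    extra <- setdiff(rownames(y$calls), rownames(x$calls))
    missing <- setdiff(rownames(x$calls), rownames(y$calls))
    if (length(extra) || length(missing))
      stop("scorer ", who, " covers different structures; offending ids: ",
           paste(c(extra, missing), collapse = ", "), call. = FALSE)
    if (!identical(x$days, y$days))
      stop("scorer ", who, " uses a different session grid", call. = FALSE)
  }
  align_check(calls_a, calls_b, "B")
  b <- calls_b$calls[rownames(calls_a$calls), , drop = FALSE]
  a <- calls_a$calls
  cc <- NULL
  if (!is.null(calls_c)) {
    stopifnot(inherits(calls_c, "presence_matrix"))
    align_check(calls_a, calls_c, "C")
    cc <- calls_c$calls[rownames(a), , drop = FALSE]
  }
  agree <- (a == b) | (is.na(a) & is.na(b))
  agree[is.na(agree)] <- FALSE
  out <- a
  disagree <- which(!agree, arr.ind = TRUE)
  disc <- data.frame(structure_id = character(), session_day = numeric(),
                     call_a = integer(), call_b = integer(),
                     resolution = integer())
  if (nrow(disagree)) {
    res <- if (is.null(cc)) rep(NA_integer_, nrow(disagree))
           else cc[disagree]
    out[disagree] <- res
    disc <- data.frame(
      structure_id = rownames(a)[disagree[, 1]],
      session_day = calls_a$days[disagree[, 2]],
      call_a = a[disagree], call_b = b[disagree], resolution = res,
      stringsAsFactors = FALSE)
    disc <- disc[order(disc$structure_id, disc$session_day), ]
    rownames(disc) <- NULL
  }
  rec <- calls_a$structures
  tidy <- data.frame(
    animal_id = rep(rec$animal_id, times = ncol(out)),
    field_id = rep(rec$field_id, times = ncol(out)),
    structure_id = rep(rec$structure_id, times = ncol(out)),
    kind = rep(rec$kind, times = ncol(out)),
    session_day = rep(calls_a$days, each = nrow(out)),
    present = as.integer(out),
    stringsAsFactors = FALSE)
  list(matrix = build_presence_matrix(tidy, policy = "split"),
       discrepancies = disc)
}
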
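# The presence matrix: structures x imaging sessions, the substrate of all
# dynamics metrics. Cells are 1 (present), 0 (absent) or NA (censored:
# scorer disagreement, occlusion). Presence must be contiguous -- a
# structure that disappears and "reappears" is, by field convention, a new
# structure, and the constructor enforces that.

new_presence_matrix <- function(calls, days, structures, validate = TRUE) {
  stopifnot(is.matrix(calls), nrow(calls) == nrow(structures),
            ncol(calls) == length(days))
  storage.mode(calls) <- "integer"
  rownames(calls) <- structures$structure_id
  colnames(calls) <- as.character(days)
  pm <- structure(list(calls = calls, days = as.numeric(days),
                       structures = structures),
                  class = "presence_matrix")
  if (validate) validate_presence_matrix(pm)
  pm
}

validate_presence_matrix <- function(pm) {
  if (is.unsorted(pm$days, strictly = TRUE))
    stop("session days must be strictly increasing", call. = FALSE)
  if (nrow(pm$calls) == 0L) return(invisible(pm))
  bad <- !vapply(seq_len(nrow(pm$calls)),
                 function(i) is_contiguous(pm$calls[i, ]), logical(1))
  if (any(bad))
    stop("non-contiguous presence (resurrection) for structure(s): ",
         paste(pm$structures$structure_id[bad], collapse = ", "),
         call. = FALSE)
  first_day <- unname(apply(pm$calls, 1L, function(x) {
    j <- which(!is.na(x) & x == 1L)[1]
    if (is.na(j)) NA_real_ else pm$days[j]
  }))
  if (!isTRUE(all.equal(first_day, unname(pm$structures$birth_day))))
    stop("`birth_day` must equal the first session with a present call",
         call. = FALSE)
  invisible(pm)
}

# Contiguity among observed (non-censored) calls: no present call after an
# absent call that itself follows a present call.
is_contiguous <- function(x) {
  x <- x[!is.na(x)]
  p <- which(x == 1L)
  if (length(p) == 0L) return(TRUE)
  all(x[seq(min(p), max(p))] == 1L)
}

#' Assemble a presence matrix from tidy annotation rows
#'
#' Takes one row per structure x session (`animal_id`, `field_id`,
#' `structure_id`, `session_day`, `present`, optionally `kind`) and builds
#' the structures-by-sessions presence matrix on which all dynamics metrics
#' operate. `present` is 1/0/`NA` (`NA` = censored). Every structure must
#' carry a row for every session day of its field.
#'
#' A present-after-absent pattern violates the no-resurrection convention.
#' Under the default `"split"` policy each contiguous run of presence
#' becomes its own structure (ids suffixed `#2`, `#3`, ...), mirroring the
#' convention that a reappearing structure is a new one; under `"strict"`
#' the offending structures are rejected by name.
#'
#' @param records Data frame of tidy annotation rows.
#' @param policy `"split"` (default) or `"strict"`; see Details.
#' @param kind Default structure kind (`"spine"`, `"bouton"`, ...) used
#'   when `records` has no `kind` column.
#' @return A `presence_matrix` object.
#' @examples
#' rec <- expand.grid(structure_id = c("s1", "s2"),
#'                    session_day = c(0, 4, 8, 12))
#' rec$animal_id <- "a1"; rec$field_id <- "f1"
#' rec$present <- as.integer(rec$structure_id == "s1" | rec$session_day < 8)
#' pm <- build_presence_matrix(rec)
#' @export
build_presence_matrix <- function(records, policy = c("split", "strict"),
                                  kind = "spine") {
  policy <- match.arg(policy)
  records <- as.data.frame(records)
  need <- c("structure_id", "session_day", "present")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("`records` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) {
    meta <- data.frame(structure_id = character(), animal_id = character(),
                       field_id = character(), kind = character(),
                       birth_day = numeric(), stringsAsFactors = FALSE)
    return(new_presence_matrix(matrix(integer(), 0L, 0L), numeric(0),
                               meta))
  }
  if (is.null(records$animal_id)) records$animal_id <- "a1"
  if (is.null(records$field_id)) records$field_id <- "f1"
  if (is.null(records$kind)) records$kind <- kind
  records$.uid <- paste(records$animal_id, records$field_id,
                        records$structure_id, sep = "\r")

  dup <- duplicated(records[c(".uid", "session_day")])
  if (any(dup))
    stop("duplicate (structure, session) rows, e.g. structure ",
         records$structure_id[dup][1], " at day ",
         records$session_day[dup][1], call. = FALSE)

  days <- sort(unique(records$session_day))
  uids <- unique(records$.uid)
  idx_u <- match(records$.uid, uids)
  idx_d <- match(records$session_day, days)
  calls <- matrix(NA_integer_, length(uids), length(days))
  calls[cbind(idx_u, idx_d)] <- as.integer(records$present)
  covered <- matrix(FALSE, length(uids), length(days))
  covered[cbind(idx_u, idx_d)] <- TRUE
  if (!all(covered))
    stop("inconsistent session grid: structure(s) missing rows for some ",
         "session days", call. = FALSE)

  meta <- records[!duplicated(records$.uid),
                  c("structure_id", "animal_id", "field_id", "kind")]
  meta <- meta[match(uids, records$.uid[!duplicated(records$.uid)]), ]

  out_calls <- list(); out_meta <- list()
  for (i in seq_along(uids)) {
    runs <- presence_runs(calls[i, ])
    if (length(runs) > 1L && policy == "strict")
      stop("non-contiguous presence (resurrection) for structure(s): ",
           meta$structure_id[i], call. = FALSE)
    if (length(runs) <= 1L) {
      out_calls[[length(out_calls) + 1L]] <- calls[i, ]
      out_meta[[length(out_meta) + 1L]] <- meta[i, ]
    } else {
      for (k in seq_along(runs)) {
        row <- integer(length(days))
        row[is.na(calls[i, ])] <- NA_integer_
        row[runs[[k]]] <- 1L
        m <- meta[i, ]
        if (k > 1L)
          m$structure_id <- paste0(m$structure_id, "#", k)
        out_calls[[length(out_calls) + 1L]] <- row
        out_meta[[length(out_meta) + 1L]] <- m
      }
    }
  }
  calls <- do.call(rbind, out_calls)
  meta <- do.call(rbind, out_meta)
  rownames(meta) <- NULL
  meta$birth_day <- apply(calls, 1L, function(x) {
    j <- which(!is.na(x) & x == 1L)[1]
    if (is.na(j)) NA_real_ else days[j]
  })
  new_presence_matrix(calls, days, meta)
}

# Indices of maximal runs of present calls (ignoring censored cells).
presence_runs <- function(x) {
  p <- which(!is.na(x) & x == 1L)
  if (length(p) == 0L) return(list())
  obs <- which(!is.na(x))
  pos <- match(p, obs)                    # ranks among observed sessions
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  lapply(seq_len(length(brk) - 1L),
         function(k) p[(brk[k] + 1L):brk[k + 1L]])
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d structures x %d sessions (days %s)\n",
              nrow(x$calls), length(x$days),
              paste(x$days, collapse = ", ")))
  cat(sprintf("  animals: %d   kinds: %s   censored cells: %d\n",
              length(unique(x$structures$animal_id)),
              paste(unique(x$structures$kind), collapse = "/"),
              sum(is.na(x$calls))))
  invisible(x)
}

#' @export
as.data.frame.presence_matrix <- function(x, ...) {
  n <- nrow(x$calls); s <- length(x$days)
  data.frame(
    animal_id = rep(x$structures$animal_id, times = s),
    field_id = rep(x$structures$field_id, times = s),
    structure_id = rep(x$structures$structure_id, times = s),
    kind = rep(x$structures$kind, times = s),
    session_day = rep(x$days, each = n),
    present = as.integer(x$calls),
    stringsAsFactors = FALSE)
}

#' Number of structures / session days of a presence matrix
#'
#' @param pm A `presence_matrix`.
#' @return `n_structures()`: integer count of structure rows;
#'   `session_days()`: numeric vector of imaging-session day offsets.
#' @export
n_structures <- function(pm) nrow(pm$calls)

#' @rdname n_structures
#' @export
session_days <- function(pm) pm$days

# Subset rows of a presence matrix, keeping metadata aligned.
pm_subset <- function(pm, idx) {
  new_presence_matrix(pm$calls[idx, , drop = FALSE], pm$days,
                      pm$structures[idx, , drop = FALSE], validate = FALSE)
}
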
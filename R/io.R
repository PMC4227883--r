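# Round-tripping the tidy delimited formats: presence tables, bouton
# ratio series, and gap-cross trial logs (event streams as a JSON column).
# Every writer emits a sidecar JSON recording the generating parameters
# and seed so a run can be reproduced exactly.

write_sidecar <- function(path, params = NULL, seed = NULL, extra = list()) {
  meta <- c(list(file = basename(path),
                 package_version = as.character(utils::packageVersion("spinegap")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            if (!is.null(seed)) list(seed = seed),
            if (!is.null(params)) list(params = unclass(params)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(paste0(path, ".json"))
}

#' Write / read a presence matrix as tidy delimited text
#'
#' One row per structure x session with columns `animal_id`, `field_id`,
#' `structure_id`, `kind`, `session_day`, `present` (1/0, empty =
#' censored). `write_presence()` also emits `<path>.json` with the
#' generator parameters and seed when given.
#'
#' @param pm A `presence_matrix`.
#' @param path Output CSV path.
#' @param params,seed Optional generator parameters / seed recorded in the
#'   sidecar.
#' @return `write_presence()`: the path, invisibly. `read_presence()`: a
#'   `presence_matrix`.
#' @export
write_presence <- function(pm, path, params = NULL, seed = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  utils::write.csv(as.data.frame(pm), path, row.names = FALSE, na = "")
  write_sidecar(path, params, seed,
                extra = list(n_structures = n_structures(pm),
                             session_days = session_days(pm)))
  invisible(path)
}

#' @rdname write_presence
#' @inheritParams build_presence_matrix
#' @export
read_presence <- function(path, policy = c("split", "strict")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_presence_matrix(df, policy = match.arg(policy))
}

#' Write / read bouton brightness-ratio series
#'
#' Tidy CSV with columns `animal_id`, `field_id`, `structure_id`,
#' `session_day`, `ratio`. Hidden ground-truth labels attached by the
#' simulator are written to a separate `<path>.truth.csv`, never into the
#' analysis-facing file.
#'
#' @param series A `bouton_series` data frame.
#' @param path Output CSV path.
#' @param params,seed Optional generator parameters / seed for the sidecar.
#' @param write_truth Also write the hidden true type labels (if present)
#'   to `<path>.truth.csv`.
#' @return `write_bouton_series()`: the path, invisibly;
#'   `read_bouton_series()`: a `bouton_series` data frame.
#' @export
write_bouton_series <- function(series, path, params = NULL, seed = NULL,
                                write_truth = FALSE) {
  cols <- c("animal_id", "field_id", "structure_id", "session_day",
            "ratio")
  utils::write.csv(as.data.frame(series)[cols], path, row.names = FALSE,
                   na = "")
  truth <- attr(series, "truth")
  if (write_truth && !is.null(truth))
    utils::write.csv(truth$types, paste0(path, ".truth.csv"),
                     row.names = FALSE)
  write_sidecar(path, params, seed)
  invisible(path)
}

#' @rdname write_bouton_series
#' @export
read_bouton_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("bouton_series", "data.frame")
  df
}

#' Write / read gap-cross trial logs
#'
#' One row per trial; the sensor event stream is serialized into a JSON
#' column `events`. `read_trials()` parses the JSON back into per-trial
#' data frames and reports malformed rows by row number.
#'
#' @param trials A `gap_trials` data frame.
#' @param path Output CSV path.
#' @param params,seed Optional agent/sampler parameters and seed for the
#'   sidecar.
#' @return `write_trials()`: the path, invisibly; `read_trials()`: a
#'   `gap_trials` data frame.
#' @export
write_trials <- function(trials, path, params = NULL, seed = NULL) {
  stopifnot(is.data.frame(trials))
  flat <- as.data.frame(trials[setdiff(names(trials), "events")])
  flat$events <- vapply(trials$events, function(e)
    as.character(jsonlite::toJSON(e, digits = NA)), character(1))
  utils::write.csv(flat, path, row.names = FALSE)
  write_sidecar(path, params, seed, extra = list(n_trials = nrow(trials)))
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(jsonlite::fromJSON(df$events[i]), error = function(e) e)
  })
  bad <- which(vapply(parsed, inherits, logical(1), "error"))
  if (length(bad))
    stop("malformed event JSON in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$events <- lapply(parsed, as.data.frame)
  class(df) <- c("gap_trials", "data.frame")
  df
}
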
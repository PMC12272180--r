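#' Write and read the simulator's on-disk containers
#'
#' Plain-text interchange formats: the trial table as CSV (one row per
#' trial; sequence list-columns are serialized to compact JSON strings),
#' traces and recordings as CSV sample matrices with a JSON sidecar
#' carrying the sampling rate, channel labels and trigger list, and
#' permutation results as JSON.
#'
#' @param design a `trial_table`.
#' @param path output CSV path.
#' @return `write_*` functions invisibly return the path(s) written;
#'   `read_trial_table` returns the table with sequence columns restored.
#' @name container-io
NULL

#' @rdname container-io
#' @export
write_trial_table <- function(design, path) {
  out <- design
  for (col in c("encoding_seq", "probe_seq", "intervening_seq")) {
    if (!is.null(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(s) {
        if (is.null(s)) "" else
          as.character(jsonlite::toJSON(unclass(s), auto_unbox = TRUE,
                                        digits = NA))
      }, character(1))
    }
  }
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' @rdname container-io
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("encoding_seq", "probe_seq", "intervening_seq")) {
    if (!is.null(tab[[col]])) {
      tab[[col]] <- lapply(tab[[col]], function(s) {
        if (is.na(s) || s == "") NULL else jsonlite::fromJSON(s)
      })
    }
  }
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' @rdname container-io
#' @param recording an `eeg_recording` or `pupil_trace`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
write_recording <- function(recording, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  if (inherits(recording, "eeg_recording")) {
    m <- t(recording$samples)
    colnames(m) <- recording$channels
    utils::write.csv(data.frame(time = recording$time, m, check.names = FALSE),
                     csv, row.names = FALSE)
    meta <- list(kind = "eeg", rate = recording$rate,
                 channels = recording$channels,
                 triggers = recording$triggers)
  } else {
    utils::write.csv(data.frame(time = recording$time,
                                samples = recording$samples), csv,
                     row.names = FALSE)
    meta <- list(kind = "pupil", rate = recording$rate, eye = recording$eye)
  }
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, json))
}

#' @rdname container-io
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  tab <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  if (identical(meta$kind, "eeg")) {
    X <- t(as.matrix(tab[, -1, drop = FALSE]))
    structure(list(samples = X, channels = meta$channels, rate = meta$rate,
                   time = tab$time, triggers = meta$triggers),
              class = "eeg_recording")
  } else {
    structure(list(samples = tab$samples, time = tab$time, rate = meta$rate,
                   eye = meta$eye, blink_truth = NULL, clean = NULL),
              class = "pupil_trace")
  }
}

#' @rdname container-io
#' @param result a `permutation_result`.
#' @export
write_permutation_json <- function(result, path) {
  payload <- list(t_observed = result$t_observed,
                  p_values = result$p_values,
                  significant = result$significant,
                  n_iterations = result$n_iterations)
  jsonlite::write_json(payload[!vapply(payload, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
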
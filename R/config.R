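#' Experiment configuration
#'
#' Bundles the structural parameters of the dual-task experiment: the
#' blocked condition design (working-memory modality x domain crossed with
#' the intervening-task condition), trial counts, phase durations and
#' recording rates. Defaults reproduce the study design this package
#' emulates: blocks of 20 trials, 40 trials per condition cell, a 1.5 s
#' pre-trial baseline, a 5.5 s retention interval, and an intervening task
#' starting 2 s after the offset of the final encoding stimulus.
#'
#' @param n_participants number of simulated participants.
#' @param trials_per_block trials in one block (even; a block holds a single
#'   condition cell with balanced same/different trials).
#' @param trials_per_combination total trials per condition cell; must be a
#'   multiple of `trials_per_block`.
#' @param pupil_rate pupillometry sampling rate in Hz.
#' @param eeg_rate EEG synthesis/analysis sampling rate in Hz (the raw
#'   acquisition mode is 2048 Hz; analyses run at 256 Hz).
#' @param baseline_duration pre-trial baseline, seconds.
#' @param retention_duration working-memory retention interval, seconds.
#' @param intervening_onset onset of the intervening sequence, seconds after
#'   the offset of the final encoding stimulus.
#' @param seed integer seed from which all simulator randomness derives.
#'
#' @return An object of class `experiment_config` (a validated list).
#' @export
#'
#' @examples
#' cfg <- experiment_config(n_participants = 2, seed = 1)
#' cfg$trials_per_combination
experiment_config <- function(n_participants = 20,
                              trials_per_block = 20,
                              trials_per_combination = 40,
                              pupil_rate = 500,
                              eeg_rate = 256,
                              baseline_duration = 1.5,
                              retention_duration = 5.5,
                              intervening_onset = 2.0,
                              seed = 1L) {
  if (trials_per_block %% 2 != 0)
    stop("trials_per_block must be even (same/different trials are balanced within a block)")
  if (trials_per_combination %% trials_per_block != 0)
    stop("trials_per_block must divide trials_per_combination")
  durs <- c(baseline_duration, retention_duration, intervening_onset)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (pupil_rate <= 0 || eeg_rate <= 0) stop("sampling rates must be positive")
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_block = as.integer(trials_per_block),
    trials_per_combination = as.integer(trials_per_combination),
    wm_modalities = c("auditory", "visual"),
    wm_domains = c("temporal", "spatial"),
    intervening_conditions = c("none", "AT", "AS"),
    pupil_rate = pupil_rate,
    eeg_rate = eeg_rate,
    baseline_duration = baseline_duration,
    retention_duration = retention_duration,
    intervening_onset = intervening_onset,
    seed = as.integer(seed)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Dual-task experiment configuration\n")
  cat(sprintf("  participants: %d\n", x$n_participants))
  cat(sprintf("  condition cells: %d (modality x domain x intervening)\n",
              length(x$wm_modalities) * length(x$wm_domains) *
                length(x$intervening_conditions)))
  cat(sprintf("  trials: %d per cell in blocks of %d\n",
              x$trials_per_combination, x$trials_per_block))
  cat(sprintf("  timing: baseline %.1f s, retention %.1f s, intervening onset +%.1f s\n",
              x$baseline_duration, x$retention_duration, x$intervening_onset))
  cat(sprintf("  rates: pupil %g Hz, EEG %g Hz\n", x$pupil_rate, x$eeg_rate))
  invisible(x)
}

# Deterministic child seed from a top-level seed and a stream label.
# Keeps every sub-generator reproducible from one integer without the
# streams being trivially correlated. Always < 2^31.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(labels)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
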
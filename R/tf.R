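#' Subtract average ERPs from a continuous trial series
#'
#' Removes the phase-locked evoked response before oscillatory analysis: at
#' every stimulus timestamp the matching participant-average ERP (keyed by
#' trial phase and sequence position; banks are built per condition cell)
#' is subtracted from the continuous data, per channel. Events without a
#' bank entry are left untouched with a warning.
#'
#' @param recording an `eeg_recording`.
#' @param erp_bank named list; each entry a list with `erp` (channels x
#'   time matrix) and `time` (s relative to stimulus onset).
#' @param events data frame of events (default: the recording's triggers)
#'   with columns `time`, `phase`, `position`.
#' @param key_fun function building the bank key from an event row;
#'   defaults to `"phase.position"`.
#' @return The recording with evoked components subtracted.
#' @export
subtract_erp <- function(recording, erp_bank, events = recording$triggers,
                         key_fun = function(ev) paste(ev$phase, ev$position,
                                                      sep = ".")) {
  X <- recording$samples
  rate <- recording$rate
  for (i in seq_len(nrow(events))) {
    key <- key_fun(events[i, , drop = FALSE])
    entry <- erp_bank[[key]]
    if (is.null(entry)) {
      warning("no ERP bank entry for event key '", key, "'; skipping")
      next
    }
    i0 <- which.min(abs(recording$time - events$time[i]))
    idx <- i0 + round(entry$time * rate)
    ok <- idx >= 1 & idx <= ncol(X)
    ch <- intersect(rownames(entry$erp), recording$channels)
    X[ch, idx[ok]] <- X[ch, idx[ok], drop = FALSE] -
      entry$erp[ch, ok, drop = FALSE]
  }
  recording$samples <- X
  recording
}

#' Mirror-pad a signal for wavelet analysis
#'
#' Extends the signal by time-reversed copies of its first and last
#' `pad_s` seconds, suppressing wavelet edge artifacts:
#' `reverse(head) ++ signal ++ reverse(tail)`. [unpad()] recovers the
#' original exactly. Signals shorter than the pad are padded with their
#' full-length reflection (with a message).
#'
#' @param x numeric signal.
#' @param pad_s pad duration, s.
#' @param rate sampling rate, Hz.
#' @return The padded signal with attribute `pad` (samples added per side).
#' @export
mirror_pad <- function(x, pad_s = 5, rate = 256) {
  n <- length(x)
  P <- round(pad_s * rate)
  if (P > n) {
    message("signal shorter than pad; using full-length reflection")
    P <- n
  }
  out <- c(rev(x[seq_len(P)]), x, rev(x[(n - P + 1):n]))
  attr(out, "pad") <- P
  out
}

#' @rdname mirror_pad
#' @param padded output of [mirror_pad()].
#' @export
unpad <- function(padded) {
  P <- attr(padded, "pad")
  if (is.null(P)) stop("not a mirror-padded signal (no pad attribute)")
  n <- length(padded) - 2 * P
  out <- padded[(P + 1):(P + n)]
  attributes(out) <- NULL
  out
}

# complex Morlet wavelet at frequency f with fixed cycle count; unit-energy
# normalized, odd length, support +/- 4 Gaussian SDs
morlet_wavelet <- function(f, rate, width = 5) {
  sigma_t <- width / (2 * pi * f)
  half <- ceiling(4 * sigma_t * rate)
  t <- (-half:half) / rate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet time-frequency transform
#'
#' Convolves the signal with complex Morlet wavelets of fixed 5-cycle width
#' at each requested frequency (1 Hz steps by default) and returns power per
#' (frequency, time). Intended to run on a mirror-padded signal; when the
#' input carries a `pad` attribute, the padding is trimmed from the output.
#'
#' @param x numeric signal (optionally from [mirror_pad()]).
#' @param rate sampling rate, Hz.
#' @param freqs frequencies, Hz.
#' @param width wavelet width in cycles.
#' @return An object of class `tfr_map`: `power` (frequency x time),
#'   `freqs`, `rate`.
#' @export
morlet_tfr <- function(x, rate, freqs = 1:80, width = 5) {
  if (any(freqs >= rate / 2))
    stop("frequencies must be below the Nyquist rate")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  P <- attr(x, "pad")
  x <- as.numeric(x)
  n <- length(x)
  pow <- matrix(NA_real_, length(freqs), n,
                dimnames = list(as.character(freqs), NULL))
  for (i in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[i], rate, width)
    m <- length(w)
    h <- (m - 1) / 2
    nf <- stats::nextn(n + m - 1, 2)
    Y <- stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                      stats::fft(c(w, rep(0, nf - m))), inverse = TRUE) / nf
    conv_same <- Y[(h + 1):(h + n)]
    pow[i, ] <- Mod(conv_same)^2
  }
  if (!is.null(P)) pow <- pow[, (P + 1):(n - P), drop = FALSE]
  structure(list(power = pow, freqs = freqs, rate = rate), class = "tfr_map")
}

#' Convert a power map to dB change relative to baseline
#'
#' `10 * log10(power / baseline_power)` per frequency. The baseline power is
#' the per-frequency mean over the pre-trial baseline window, averaged
#' across all of a participant's conditions before any condition split, so
#' permuting condition labels leaves all dB values unchanged.
#'
#' @param tfr a `tfr_map` (or bare power matrix, frequency x time).
#' @param baseline_power numeric vector, one value per frequency.
#' @return The map with power replaced by dB change.
#' @export
db_baseline <- function(tfr, baseline_power) {
  pow <- if (inherits(tfr, "tfr_map")) tfr$power else tfr
  if (length(baseline_power) != nrow(pow))
    stop("need one baseline power value per frequency")
  if (any(baseline_power <= 0)) stop("baseline power must be positive")
  db <- 10 * log10(sweep(pow, 1, baseline_power, "/"))
  if (inherits(tfr, "tfr_map")) {
    tfr$power <- db
    tfr$units <- "dB"
    tfr
  } else db
}

#' Individual alpha frequency and alpha power time course
#'
#' The individual alpha frequency (IAF) is the integer frequency in the
#' alpha band at which the absolute baseline-relative power change,
#' averaged over the trimmed retention window (first and last 500 ms
#' excluded), is maximal; ties break toward the lower frequency. The alpha
#' time course is the mean dB power over IAF - 1, IAF and IAF + 1 Hz across
#' the full map.
#'
#' @param db_map `tfr_map` in dB (typically at channel Pz) or matrix.
#' @param time time vector (s) for the map columns.
#' @param retention_window length-2 numeric, retention interval in s.
#' @param band alpha band searched, Hz.
#' @param trim seconds excluded at each retention edge.
#' @param freqs frequencies of the map rows (taken from a `tfr_map`).
#' @return List: `iaf` (Hz), `timecourse` (dB per time point), `time`,
#'   `band_change` (mean retention dB per candidate frequency).
#' @export
individual_alpha <- function(db_map, time, retention_window = c(0, 5.5),
                             band = c(8, 12), trim = 0.5, freqs = NULL) {
  if (inherits(db_map, "tfr_map")) {
    freqs <- db_map$freqs
    db_map <- db_map$power
  }
  if (is.null(freqs)) stop("freqs required when db_map is a bare matrix")
  cand <- seq(band[1], band[2])
  need <- c(band[1] - 1, band[2] + 1)
  if (!all(c(cand, need) %in% freqs))
    stop("alpha band (with 1 Hz margin) outside computed frequencies")
  ret <- time >= retention_window[1] + trim & time < retention_window[2] - trim
  if (!any(ret)) stop("trimmed retention window is empty")
  change <- vapply(cand, function(f)
    mean(db_map[match(f, freqs), ret]), numeric(1))
  iaf <- cand[which.max(abs(change))]   # which.max takes the first (lowest) tie
  rows <- match(c(iaf - 1, iaf, iaf + 1), freqs)
  list(iaf = iaf, timecourse = colMeans(db_map[rows, , drop = FALSE]),
       time = time, band_change = stats::setNames(change, cand))
}

#' Windowed permutation contrasts on alpha time courses
#'
#' Applies the windowed percentile permutation test to each requested pair
#' of conditions in each time region of interest (defaults: the window
#' spanning the intervening task, 2-3.5 s into retention, and the window
#' just after it, 3.5-5 s).
#'
#' @param timecourses named list of participants x time matrices, one per
#'   condition (domain-collapsed).
#' @param time time vector (s).
#' @param contrasts list of length-2 character vectors naming condition
#'   pairs; defaults to all pairs.
#' @param windows list of length-2 numeric windows, s.
#' @param n_iter,alpha,seed passed to [windowed_percentile_test()].
#' @return Nested list `result[[contrast]][[window]]`, each a
#'   `permutation_result`.
#' @export
alpha_contrasts <- function(timecourses, time, contrasts = NULL,
                            windows = list(c(2, 3.5), c(3.5, 5)),
                            n_iter = 2000, alpha = 0.05, seed = 1L) {
  conds <- names(timecourses)
  if (is.null(contrasts))
    contrasts <- utils::combn(conds, 2, simplify = FALSE)
  out <- list()
  for (ct in contrasts) {
    key <- paste(ct, collapse = "_vs_")
    out[[key]] <- list()
    for (w in windows) {
      wkey <- sprintf("%g-%gs", w[1], w[2])
      out[[key]][[wkey]] <- windowed_percentile_test(
        timecourses[[ct[1]]], timecourses[[ct[2]]], time, w,
        n_iter = n_iter, alpha = alpha,
        seed = derive_seed(seed, key, wkey))
    }
  }
  out
}
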
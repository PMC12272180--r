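#' Pupil response model
#'
#' Generative model for single-trial pupil-diameter traces: a constant
#' baseline plus an event-related dilation (a gamma-shaped impulse response
#' convolved with stimulus onsets, scaled per condition cell), an
#' anticipatory ramp ahead of the intervening task in auditory-temporal
#' working-memory cells, Gaussian sensor noise, and blink dropouts in which
#' the tracker loses the pupil (samples fall steeply to zero).
#'
#' The impulse response is `h(t) = (t/t_max)^s * exp(s * (1 - t/t_max))`,
#' unit peak at `t_max`. The default `t_max` is set so that the summed
#' dilation over a four-stimulus encoding sequence peaks roughly 0.7 s after
#' the offset of the final encoding stimulus.
#'
#' @param baseline_level baseline diameter, arbitrary tracker units.
#' @param kernel_t_max impulse-response peak latency, s.
#' @param kernel_shape gamma shape parameter (dimensionless).
#' @param encoding_gain named vector of dilation gain per
#'   working-memory cell key `"modality.domain"` (a.u. per stimulus).
#' @param intervening_gain named vector per key
#'   `"intervening.modality.domain"` (a.u. per stimulus).
#' @param anticipatory_gain named vector per `"modality.domain"`; a linear
#'   effort ramp from encoding offset to intervening onset, peak a.u.
#' @param blink_rate blink events per second.
#' @param blink_duration_range min/max blink duration, s.
#' @param noise_sd Gaussian noise SD, a.u.
#' @return An object of class `pupil_model`.
#' @export
pupil_model <- function(baseline_level = 1000,
                        kernel_t_max = 1.1,
                        kernel_shape = 10.1,
                        encoding_gain = c(auditory.temporal = 60,
                                          auditory.spatial = 90,
                                          visual.temporal = 60,
                                          visual.spatial = 60),
                        intervening_gain = default_intervening_pupil_gain(),
                        anticipatory_gain = c(auditory.temporal = 25),
                        blink_rate = 0.15,
                        blink_duration_range = c(0.1, 0.3),
                        noise_sd = 10) {
  stopifnot(all(encoding_gain >= 0), all(intervening_gain >= 0),
            kernel_t_max > 0, kernel_shape > 0, noise_sd >= 0,
            blink_rate >= 0)
  structure(as.list(environment()), class = "pupil_model")
}

#' @rdname pupil_model
#' @export
default_intervening_pupil_gain <- function() {
  # second dilation scales with WM load similarity; AT task > AS task overall
  g <- c(AT.auditory.temporal = 90, AT.auditory.spatial = 70,
         AT.visual.temporal = 55, AT.visual.spatial = 55,
         AS.auditory.temporal = 75, AS.auditory.spatial = 60,
         AS.visual.temporal = 45, AS.visual.spatial = 45)
  g
}

pupil_kernel <- function(t, t_max, shape) {
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- (t[pos] / t_max)^shape * exp(shape * (1 - t[pos] / t_max))
  h
}

# convolve unit impulses at `event_times` (s) with the dilation kernel,
# evaluated on the trace time axis
dilation_component <- function(time, event_times, model) {
  out <- numeric(length(time))
  for (ev in event_times)
    out <- out + pupil_kernel(time - ev, model$kernel_t_max, model$kernel_shape)
  out
}

#' Simulate one trial's pupil trace
#'
#' Samples a pupil-diameter trace at `rate` Hz from the start of the
#' pre-trial baseline through the last sample before probe onset, with time
#' zero at the offset of the final encoding stimulus. Blink dropouts
#' replace the signal with a steep fall to zero (two transition samples per
#' flank), the occlusion signature the cleaning pipeline detects.
#'
#' @param trial one row of a `trial_table` with stimuli attached, or a list
#'   with fields `wm_modality`, `wm_domain`, `intervening`, `encoding_seq`,
#'   `intervening_seq`.
#' @param model a [pupil_model()].
#' @param rate sampling rate, Hz.
#' @param baseline_duration,retention_duration,intervening_onset timing
#'   parameters, s (see [experiment_config()]).
#' @param seed optional integer seed.
#' @return A `pupil_trace`: `samples`, `time` (s, 0 = encoding offset),
#'   `rate`, `eye`, `blink_truth` (logical ground-truth occlusion mask) and
#'   `clean` (the noise- and blink-free trace) for validation.
#' @export
simulate_pupil_trial <- function(trial, model = pupil_model(), rate = 500,
                                 baseline_duration = 1.5,
                                 retention_duration = 5.5,
                                 intervening_onset = 2.0,
                                 seed = NULL) {
  trial <- as_trial(trial)
  enc <- trial$encoding_seq
  if (is.null(enc)) stop("trial has no encoding sequence; run generate_stimuli() first")
  if (!is.null(seed)) set.seed(seed)

  t0 <- -(baseline_duration + enc$offset)   # baseline start
  t1 <- retention_duration                  # probe onset
  time <- seq(t0, t1 - 1 / rate, by = 1 / rate)

  cell <- paste(trial$wm_modality, trial$wm_domain, sep = ".")
  enc_gain <- lookup_logodds(model$encoding_gain, cell, 0)
  trace <- rep(model$baseline_level, length(time)) +
    enc_gain * dilation_component(time, enc$onsets - enc$offset, model)

  if (!is.null(trial$intervening) && trial$intervening != "none" &&
      !is.null(trial$intervening_seq)) {
    ig <- lookup_logodds(model$intervening_gain,
                         paste(trial$intervening, cell, sep = "."), 0)
    ev <- intervening_onset + trial$intervening_seq$onsets
    trace <- trace + ig * dilation_component(time, ev, model)
    ag <- lookup_logodds(model$anticipatory_gain, cell, 0)
    if (ag > 0) {
      ramp <- pmax(0, pmin(1, time / intervening_onset))
      trace <- trace + ag * ramp
    }
  }

  clean <- trace
  trace <- trace + stats::rnorm(length(time), 0, model$noise_sd)

  blink_truth <- rep(FALSE, length(time))
  if (model$blink_rate > 0) {
    n_blinks <- stats::rpois(1, model$blink_rate * (t1 - t0))
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, t0, t1)
      durs <- stats::runif(n_blinks, model$blink_duration_range[1],
                           model$blink_duration_range[2])
      for (b in seq_len(n_blinks)) {
        idx <- which(time >= starts[b] & time <= starts[b] + durs[b])
        if (length(idx) == 0) next
        trace[idx] <- 0
        # steep flanks: two transition samples on each side
        for (k in 1:2) {
          lo <- min(idx) - k; hi <- max(idx) + k
          frac <- k / 3
          if (lo >= 1) trace[lo] <- trace[lo] * frac
          if (hi <= length(trace)) trace[hi] <- trace[hi] * frac
        }
        blink_truth[pmax(1, min(idx) - 2):pmin(length(time), max(idx) + 2)] <- TRUE
      }
    }
  }

  structure(list(samples = trace, time = time, rate = rate, eye = "left",
                 blink_truth = blink_truth, clean = clean),
            class = "pupil_trace")
}

as_trial <- function(trial) {
  if (is.data.frame(trial)) {
    stopifnot(nrow(trial) == 1)
    out <- as.list(trial)
    for (f in c("encoding_seq", "probe_seq", "intervening_seq"))
      if (!is.null(out[[f]])) out[[f]] <- out[[f]][[1]]
    out
  } else trial
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("pupil_trace: %d samples at %g Hz, t = [%.2f, %.2f] s, eye %s\n",
              length(x$samples), x$rate, min(x$time), max(x$time), x$eye))
  cat(sprintf("  occluded samples: %d (%.1f%%)\n", sum(x$blink_truth),
              100 * mean(x$blink_truth)))
  invisible(x)
}
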
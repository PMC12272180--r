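#' EEG generative model
#'
#' Synthesizes single-trial EEG as the superposition of (a) stimulus-locked
#' event-related potential templates (Gaussian-windowed N1, P2 and P3
#' components with fixed fronto-central / parietal topographies) inserted at
#' every stimulus onset, with the P2 magnitude of intervening-task stimuli
#' scaled per condition cell; (b) an alpha-band sinusoid at the
#' participant's individual alpha frequency with random phase per trial and
#' a condition- and trial-phase-specific power envelope, strongest at Pz
#' (elevated during auditory working-memory retention, suppressed then
#' recovering for visual working memory, and transiently suppressed while an
#' intervening task runs); and (c) 1/f ("pink") background noise. A
#' configurable fraction of stimulus epochs receives a high-amplitude
#' transient exceeding the 100 uV peak-to-peak artifact criterion.
#'
#' @param channels channel labels; must contain the fronto-central and
#'   parieto-occipital sets used by the analysis pipelines plus two
#'   mastoids (`M1`, `M2`).
#' @param erp_components data frame with one row per component: `name`,
#'   `latency` (s), `width` (s, Gaussian SD), `amplitude` (uV).
#' @param p2_gain named vector of multiplicative P2 gains per intervening
#'   cell key `"intervening.modality.domain"`.
#' @param alpha_frequencies named vector, Hz in \[8, 12\], one entry per
#'   participant id (characters of the ids); participants missing from the
#'   vector are assigned reproducibly from the model seed at simulation.
#' @param alpha_amp alpha amplitude at Pz, uV.
#' @param alpha_envelope list with `auditory` and `visual` elements, each a
#'   list of per-phase multipliers (`baseline`, `encoding`, `retention`,
#'   `probe`); `retention` may be length 2 for a linear ramp across the
#'   retention interval.
#' @param intervening_alpha_suppression multiplicative alpha suppression
#'   applied while the intervening task runs (1 = none).
#' @param pink_noise_sd background-noise SD, uV.
#' @param artifact_rate probability that a stimulus epoch receives an
#'   artifact transient.
#' @return An object of class `eeg_model`.
#' @export
eeg_model <- function(channels = default_channels(),
                      erp_components = default_erp_components(),
                      p2_gain = default_p2_gain(),
                      alpha_frequencies = numeric(0),
                      alpha_amp = 3,
                      alpha_envelope = default_alpha_envelope(),
                      intervening_alpha_suppression = 0.45,
                      pink_noise_sd = 5,
                      artifact_rate = 0.02) {
  need <- c("Fz", "AFz", "Cz", "F1", "F2", "FCz", "FC1", "FC2", "Pz",
            "O1", "O2", "PO3", "PO4", "PO7", "PO8", "M1", "M2")
  missing <- setdiff(need, channels)
  if (length(missing)) stop("channel layout missing: ", paste(missing, collapse = ", "))
  if (length(alpha_frequencies) &&
      (any(alpha_frequencies < 8) || any(alpha_frequencies > 12)))
    stop("alpha frequencies must lie in [8, 12] Hz")
  stopifnot(pink_noise_sd >= 0, artifact_rate >= 0, artifact_rate <= 1)
  structure(as.list(environment())[c("channels", "erp_components", "p2_gain",
                                     "alpha_frequencies", "alpha_amp",
                                     "alpha_envelope",
                                     "intervening_alpha_suppression",
                                     "pink_noise_sd", "artifact_rate")],
            class = "eeg_model")
}

#' @rdname eeg_model
#' @export
default_channels <- function()
  c("Fz", "AFz", "Cz", "F1", "F2", "FCz", "FC1", "FC2", "Pz",
    "O1", "O2", "PO3", "PO4", "PO7", "PO8", "M1", "M2")

#' @rdname eeg_model
#' @export
default_erp_components <- function()
  data.frame(name = c("N1", "P2", "P3"),
             latency = c(0.100, 0.205, 0.320),
             width = c(0.020, 0.012, 0.050),
             amplitude = c(-4, 5, 3))

#' @rdname eeg_model
#' @export
default_p2_gain <- function() {
  # smaller P2 when WM content overlaps the intervening task in modality;
  # domain-match suppression strongest for the spatial intervening task
  c(AT.auditory.temporal = 0.70, AT.auditory.spatial = 0.75,
    AT.visual.temporal = 1.00, AT.visual.spatial = 1.10,
    AS.auditory.temporal = 0.75, AS.auditory.spatial = 0.70,
    AS.visual.temporal = 1.10, AS.visual.spatial = 0.90)
}

#' @rdname eeg_model
#' @export
default_alpha_envelope <- function()
  list(auditory = list(baseline = 1.0, encoding = 1.4, retention = 1.6,
                       probe = 1.0),
       visual = list(baseline = 1.0, encoding = 0.55, retention = c(0.7, 1.3),
                     probe = 1.0))

# topographic weights over the default layout
topo_weights <- function(channels, kind) {
  w <- stats::setNames(numeric(length(channels)), channels)
  frontocentral <- c(Fz = 1, FCz = 1, Cz = 1, FC1 = 0.95, FC2 = 0.95,
                     AFz = 0.8, F1 = 0.8, F2 = 0.8, Pz = 0.4,
                     O1 = 0.15, O2 = 0.15, PO3 = 0.2, PO4 = 0.2,
                     PO7 = 0.15, PO8 = 0.15)
  parietal <- c(Pz = 1, PO3 = 0.8, PO4 = 0.8, PO7 = 0.7, PO8 = 0.7,
                O1 = 0.7, O2 = 0.7, Cz = 0.3, Fz = 0.1, AFz = 0.1,
                F1 = 0.1, F2 = 0.1, FCz = 0.2, FC1 = 0.2, FC2 = 0.2)
  src <- switch(kind, erp = frontocentral, p3 = parietal, alpha = parietal)
  for (ch in names(src)) if (ch %in% channels) w[ch] <- src[[ch]]
  w  # mastoids stay 0
}

# single-channel ERP template on time axis `t` (s, 0 = stimulus onset);
# p2_scale multiplies only the P2 component
erp_template <- function(t, components, p2_scale = 1) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(components))) {
    a <- components$amplitude[i] *
      (if (components$name[i] == "P2") p2_scale else 1)
    out <- out + a * exp(-(t - components$latency[i])^2 /
                           (2 * components$width[i]^2))
  }
  out
}

# 1/f-amplitude noise via FFT shaping, scaled to sd
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  nf <- n %/% 2
  phases <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, 1 / sqrt(seq_len(nf))),
                  argument = c(0, phases))
  full <- c(spec, Conj(rev(spec[2:(n - nf)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

participant_alpha <- function(model, participant, seed) {
  key <- as.character(participant)
  if (key %in% names(model$alpha_frequencies))
    return(model$alpha_frequencies[[key]])
  with_seed(derive_seed(seed, "iaf", key), sample(8:12, 1))
}

#' Simulate one trial's EEG segment
#'
#' Produces a multichannel recording spanning the pre-trial baseline through
#' the end of the probe sequence, with time zero at the offset of the final
#' encoding stimulus, plus the event-trigger list the analysis pipelines
#' consume.
#'
#' @param trial one row of a `trial_table` with stimuli attached (or an
#'   equivalent list).
#' @param model an [eeg_model()].
#' @param participant participant id (selects the individual alpha
#'   frequency).
#' @param rate sampling rate, Hz (EEG is synthesized directly at the
#'   analysis rate by default; pass 2048 to exercise the downsampler).
#' @param baseline_duration,retention_duration,intervening_onset timing, s.
#' @param seed optional integer seed (alpha-frequency assignment for
#'   participants not fixed in the model also derives from it).
#' @return An `eeg_recording`: `samples` (channels x time, uV), `channels`,
#'   `rate`, `time` (s), `triggers` (data frame: time, code, phase,
#'   position), and `alpha_frequency` used.
#' @export
simulate_eeg_trial <- function(trial, model = eeg_model(), participant = 1,
                               rate = 256,
                               baseline_duration = 1.5,
                               retention_duration = 5.5,
                               intervening_onset = 2.0,
                               seed = 1L) {
  trial <- as_trial(trial)
  enc <- trial$encoding_seq
  probe <- trial$probe_seq
  if (is.null(enc) || is.null(probe))
    stop("trial has no stimulus sequences; run generate_stimuli() first")

  t0 <- -(baseline_duration + enc$offset)
  t_probe0 <- retention_duration
  t1 <- t_probe0 + probe$offset + 0.6   # headroom for the last epoch
  time <- seq(t0, t1, by = 1 / rate)
  nch <- length(model$channels)
  nt <- length(time)
  X <- matrix(0, nch, nt, dimnames = list(model$channels, NULL))

  events <- data.frame(time = enc$onsets - enc$offset, code = 10 + seq_len(4),
                       phase = "encoding", position = seq_len(4))
  has_int <- !is.null(trial$intervening) && trial$intervening != "none" &&
    !is.null(trial$intervening_seq)
  if (has_int) {
    ev <- intervening_onset + trial$intervening_seq$onsets
    events <- rbind(events, data.frame(time = ev, code = 20 + seq_len(3),
                                       phase = "intervening",
                                       position = seq_len(3)))
  }
  events <- rbind(events, data.frame(time = t_probe0 + probe$onsets,
                                     code = 30 + seq_len(4),
                                     phase = "probe", position = seq_len(4)))

  cell <- paste(trial$wm_modality, trial$wm_domain, sep = ".")
  p2g <- if (has_int)
    lookup_logodds(model$p2_gain, paste(trial$intervening, cell, sep = "."), 1)
  else 1

  w_erp <- topo_weights(model$channels, "erp")
  for (i in seq_len(nrow(events))) {
    scale <- if (events$phase[i] == "intervening") p2g else 1
    tpl <- erp_template(time - events$time[i], model$erp_components, scale)
    X <- X + outer(w_erp, tpl)
  }

  iaf <- participant_alpha(model, participant, seed)
  if (model$alpha_amp > 0) {
    env <- alpha_envelope_series(time, trial$wm_modality, model,
                                 baseline_duration, retention_duration,
                                 intervening_onset, has_int, enc$offset)
    phase0 <- stats::runif(1, 0, 2 * pi)
    osc <- model$alpha_amp * env * sin(2 * pi * iaf * time + phase0)
    X <- X + outer(topo_weights(model$channels, "alpha"), osc)
  }

  if (model$pink_noise_sd > 0) {
    for (ch in seq_len(nch)) {
      sd_ch <- if (model$channels[ch] %in% c("M1", "M2"))
        model$pink_noise_sd * 0.2 else model$pink_noise_sd
      X[ch, ] <- X[ch, ] + pink_noise(nt, sd_ch)
    }
  }

  if (model$artifact_rate > 0) {
    hit <- stats::runif(nrow(events)) < model$artifact_rate
    for (i in which(hit)) {
      at <- events$time[i] + stats::runif(1, 0, 0.3)
      idx <- which(time >= at & time <= at + 0.05)
      if (length(idx)) {
        ch <- sample(which(!model$channels %in% c("M1", "M2")), 1)
        X[ch, idx] <- X[ch, idx] + 150 * sin(seq(0, pi, length.out = length(idx)))
      }
    }
  }

  structure(list(samples = X, channels = model$channels, rate = rate,
                 time = time, triggers = events, alpha_frequency = iaf,
                 participant = participant),
            class = "eeg_recording")
}

# piecewise alpha envelope over the trial, per working-memory modality
alpha_envelope_series <- function(time, modality, model, baseline_duration,
                                  retention_duration, intervening_onset,
                                  has_int, enc_offset) {
  e <- model$alpha_envelope[[modality]]
  env <- numeric(length(time))
  env[time < -enc_offset] <- e$baseline
  env[time >= -enc_offset & time < 0] <- e$encoding
  ret <- time >= 0 & time < retention_duration
  if (length(e$retention) == 2) {
    frac <- time[ret] / retention_duration
    env[ret] <- e$retention[1] + frac * (e$retention[2] - e$retention[1])
  } else env[ret] <- e$retention
  env[time >= retention_duration] <- e$probe
  if (has_int && model$intervening_alpha_suppression != 1) {
    win <- time >= intervening_onset & time < intervening_onset + 1.5
    env[win] <- env[win] * model$intervening_alpha_suppression
  }
  env
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples at %g Hz, t = [%.2f, %.2f] s\n",
              nrow(x$samples), ncol(x$samples), x$rate, min(x$time), max(x$time)))
  cat(sprintf("  triggers: %d; alpha frequency: %g Hz\n",
              nrow(x$triggers), x$alpha_frequency))
  invisible(x)
}

#' Measurement-level P2 amplitude generator
#'
#' Draws per-participant, per-cell P2 amplitudes directly at the
#' measurement level implied by the EEG model: the template's mean P2-window
#' amplitude times the cell's gain and a participant-specific gain, plus
#' trial-averaged measurement noise. Used for repeated-measures power
#' checks where synthesizing full raw EEG for many datasets is unnecessary.
#'
#' @param model an [eeg_model()].
#' @param n_participants participants.
#' @param n_trials trials averaged per cell.
#' @param participant_gain_sd SD of the multiplicative participant gain.
#' @param epoch_noise_sd SD of the single-epoch P2 measurement noise, uV.
#' @return Data frame: `participant`, `wm_modality`, `wm_domain`,
#'   `intervening`, `amplitude` (uV), one row per participant x cell.
#' @export
simulate_p2_table <- function(model = eeg_model(), n_participants = 20,
                              n_trials = 40, participant_gain_sd = 0.15,
                              epoch_noise_sd = 2) {
  base <- p2_window_mean(model$erp_components)
  cells <- expand.grid(intervening = c("AT", "AS"),
                       wm_modality = c("auditory", "visual"),
                       wm_domain = c("temporal", "spatial"),
                       stringsAsFactors = FALSE)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    g <- stats::rnorm(1, 1, participant_gain_sd)
    key <- paste(cells$intervening, cells$wm_modality, cells$wm_domain, sep = ".")
    mu <- base * lookup_logodds(model$p2_gain, key, 1) * g
    amp <- mu + stats::rnorm(nrow(cells), 0, epoch_noise_sd / sqrt(n_trials))
    out[[p]] <- cbind(data.frame(participant = p), cells,
                      data.frame(amplitude = amp))
  }
  do.call(rbind, out)
}

# mean template amplitude over the P2 measurement window, fronto-central
# cluster weight applied
p2_window_mean <- function(components, window = c(0.190, 0.220)) {
  t <- seq(window[1], window[2], by = 1e-4)
  cluster_w <- mean(topo_weights(default_channels(), "erp")[
    c("Fz", "FCz", "Cz", "FC1", "FC2")])
  mean(erp_template(t, components)) * cluster_w
}
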
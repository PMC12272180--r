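#' Blink-detection thresholds
#'
#' Thresholds for automatic blink detection on raw pupil traces. A sample is
#' flagged when its absolute instantaneous velocity or acceleration exceeds
#' the corresponding limit, or when its value leaves the position bounds;
#' flagged events are padded on both sides and overlapping events merged.
#' Any limit left `NULL` is derived from the trace itself: velocity and
#' acceleration limits as 10x the median absolute first/second difference
#' (scaled by the sampling rate), position bounds as median +/- 5 MAD.
#'
#' @param position_bounds length-2 numeric, tracker units.
#' @param velocity_limit units/s.
#' @param acceleration_limit units/s^2.
#' @param pad_samples samples added around each detected event.
#' @return An object of class `blink_thresholds`.
#' @export
blink_thresholds <- function(position_bounds = NULL, velocity_limit = NULL,
                             acceleration_limit = NULL, pad_samples = 10L) {
  if (!is.null(velocity_limit) && velocity_limit <= 0)
    stop("velocity_limit must be positive")
  if (!is.null(acceleration_limit) && acceleration_limit <= 0)
    stop("acceleration_limit must be positive")
  structure(list(position_bounds = position_bounds,
                 velocity_limit = velocity_limit,
                 acceleration_limit = acceleration_limit,
                 pad_samples = as.integer(pad_samples)),
            class = "blink_thresholds")
}

#' Detect blinks in a pupil trace
#'
#' @param trace a `pupil_trace` or numeric vector.
#' @param thresholds a [blink_thresholds()]; data-derived defaults if omitted.
#' @param rate sampling rate, Hz (taken from the trace when available).
#' @param extra_mask optional logical vector of additional samples to mask
#'   (the machine-readable replacement for manual segment marking).
#' @return Logical blink mask, one element per sample.
#' @export
detect_blinks <- function(trace, thresholds = blink_thresholds(), rate = NULL,
                          extra_mask = NULL) {
  x <- if (inherits(trace, "pupil_trace")) trace$samples else trace
  if (is.null(rate)) rate <- if (inherits(trace, "pupil_trace")) trace$rate else 500
  n <- length(x)
  d1 <- diff(x)
  d2 <- diff(x, differences = 2)

  # data-derived limits: 3x a high quantile of the trace's own dynamics, so
  # slow task-evoked dilations never trip them while dropout flanks (orders
  # of magnitude faster) always do; a zero limit means no dynamics at all,
  # hence nothing to flag
  vlim <- thresholds$velocity_limit
  if (is.null(vlim)) {
    vlim <- 3 * stats::quantile(abs(d1), 0.995, names = FALSE) * rate
    if (vlim == 0) vlim <- Inf
  }
  alim <- thresholds$acceleration_limit
  if (is.null(alim)) {
    alim <- 3 * stats::quantile(abs(d2), 0.995, names = FALSE) * rate^2
    if (alim == 0) alim <- Inf
  }
  # default position bounds: median +/- max(5 MAD, half the median). The
  # median is immune to occlusions (they cover < 50% by the rejection rule)
  # and the relative floor keeps task-evoked dilations inside the bounds on
  # low-noise traces while dropout-to-zero samples always fall outside.
  pb <- thresholds$position_bounds
  if (is.null(pb)) {
    m <- stats::median(x)
    w <- max(5 * stats::mad(x), 0.5 * abs(m))
    pb <- c(m - w, m + w)
  }

  mask <- x < pb[1] | x > pb[2]
  v <- abs(d1) * rate > vlim
  mask[c(v, FALSE)] <- TRUE
  mask[c(FALSE, v)] <- TRUE
  a <- abs(d2) * rate^2 > alim
  mask[c(FALSE, a, FALSE)] <- TRUE
  if (!is.null(extra_mask)) mask <- mask | extra_mask

  dilate_mask(mask, thresholds$pad_samples)
}

# pad TRUE runs by k samples on both sides; merging of overlapping events
# falls out of taking the union
dilate_mask <- function(mask, k) {
  if (k <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  out <- mask
  idx <- which(mask)
  for (off in seq_len(k)) {
    out[pmax(1, idx - off)] <- TRUE
    out[pmin(n, idx + off)] <- TRUE
  }
  out
}

mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Interpolate blink segments
#'
#' Interior masked segments are replaced by the straight line joining the
#' mean of the three clean samples preceding the segment to the mean of the
#' three following it. A segment touching the start of the window is filled
#' by back-projecting a least-squares line fit to the five clean samples
#' after it; a segment touching the end uses the mirrored rule. A segment
#' without enough clean anchor samples (3 interior, 5 at an edge) marks the
#' trace unrecoverable.
#'
#' @param trace `pupil_trace` or numeric vector.
#' @param mask logical mask from [detect_blinks()].
#' @return The trace with masked samples replaced; attribute/field
#'   `unrecoverable` is set when anchors were insufficient (samples are then
#'   left untouched for that segment).
#' @export
interpolate_blinks <- function(trace, mask) {
  is_trace <- inherits(trace, "pupil_trace")
  x <- if (is_trace) trace$samples else trace
  n <- length(x)
  if (length(mask) != n) stop("mask length must equal sample length")
  unrecoverable <- FALSE
  runs <- mask_runs(mask)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (s == 1 && e == n) { unrecoverable <- TRUE; next }
    if (s == 1) {
      anchor <- (e + 1):(e + 5)
      if (max(anchor) > n || any(mask[anchor])) { unrecoverable <- TRUE; next }
      fit <- stats::lm.fit(cbind(1, anchor), x[anchor])
      x[s:e] <- fit$coefficients[1] + fit$coefficients[2] * (s:e)
    } else if (e == n) {
      anchor <- (s - 5):(s - 1)
      if (min(anchor) < 1 || any(mask[anchor])) { unrecoverable <- TRUE; next }
      fit <- stats::lm.fit(cbind(1, anchor), x[anchor])
      x[s:e] <- fit$coefficients[1] + fit$coefficients[2] * (s:e)
    } else {
      pre <- (s - 3):(s - 1)
      post <- (e + 1):(e + 3)
      if (min(pre) < 1 || max(post) > n || any(mask[pre]) || any(mask[post])) {
        unrecoverable <- TRUE; next
      }
      a <- mean(x[pre]); b <- mean(x[post])
      frac <- (s:e - (s - 1)) / (e + 1 - (s - 1))
      x[s:e] <- a + frac * (b - a)
    }
  }
  if (is_trace) {
    trace$samples <- x
    trace$blink_mask <- mask
    trace$unrecoverable <- unrecoverable
    trace
  } else {
    attr(x, "unrecoverable") <- unrecoverable
    x
  }
}

#' Reject trials by masked-data fraction
#'
#' A trial is kept when at most `max_masked_fraction` of its trial-window
#' samples are masked; the bound is strict (a fraction of exactly 0.25 is
#' kept, anything above is rejected).
#'
#' @param masks list of logical masks (one per trial) or list of
#'   `pupil_trace` objects carrying `blink_mask`.
#' @param max_masked_fraction rejection bound.
#' @return A list with `kept` (indices), `report` (data frame: trial,
#'   fraction, rejected).
#' @export
reject_trials <- function(masks, max_masked_fraction = 0.25) {
  fr <- vapply(masks, function(m) {
    if (inherits(m, "pupil_trace")) m <- m$blink_mask
    mean(m)
  }, numeric(1))
  rejected <- fr > max_masked_fraction
  list(kept = which(!rejected),
       report = data.frame(trial = seq_along(masks), fraction = fr,
                           rejected = rejected))
}

#' Average the two eyes' traces
#'
#' Samplewise mean of the left- and right-eye traces; when only one eye is
#' available it passes through unchanged. Blink masks, when present, are
#' combined by union.
#'
#' @param left,right `pupil_trace` objects or numeric vectors; either (but
#'   not both) may be `NULL`.
#' @return The averaged trace, same type as the inputs.
#' @export
average_eyes <- function(left, right) {
  if (is.null(left) && is.null(right)) stop("no eye data supplied")
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  lx <- if (inherits(left, "pupil_trace")) left$samples else left
  rx <- if (inherits(right, "pupil_trace")) right$samples else right
  if (length(lx) != length(rx)) stop("eye traces differ in length")
  avg <- (lx + rx) / 2
  if (inherits(left, "pupil_trace")) {
    out <- left
    out$samples <- avg
    out$eye <- "mean"
    lm_ <- left$blink_mask; rm_ <- right$blink_mask
    if (!is.null(lm_) && !is.null(rm_)) out$blink_mask <- lm_ | rm_
    out
  } else avg
}

#' Z-score trials over their concatenation
#'
#' Concatenates all of one participant's kept trials, z-scores the
#' concatenation (population SD convention), and splits the result back
#' into the original trials. The output is therefore invariant to positive
#' affine rescaling of the raw diameter.
#'
#' @param trials list of numeric vectors or `pupil_trace` objects.
#' @return The trials with samples z-scored.
#' @export
zscore_concatenated <- function(trials) {
  get_s <- function(tr) if (inherits(tr, "pupil_trace")) tr$samples else tr
  all_s <- unlist(lapply(trials, get_s))
  mu <- mean(all_s)
  sdv <- sqrt(mean((all_s - mu)^2))
  if (sdv == 0) stop("concatenated trace has zero variance; cannot z-score")
  lapply(trials, function(tr) {
    if (inherits(tr, "pupil_trace")) {
      tr$samples <- (tr$samples - mu) / sdv
      tr
    } else (tr - mu) / sdv
  })
}

#' Intervening-minus-none condition difference
#'
#' Subtracts each participant's mean trace in the condition without the
#' intervening task from the matching condition with it, then summarizes
#' across participants.
#'
#' @param with_task,without_task numeric matrices, participants x time, on
#'   a shared time base.
#' @param time optional time vector (s) carried into the result.
#' @return List: `diff` (participants x time), `mean`, `sem`, `time`.
#' @export
condition_difference <- function(with_task, without_task, time = NULL) {
  if (!all(dim(with_task) == dim(without_task)))
    stop("condition matrices must share participants and time base")
  d <- with_task - without_task
  n <- nrow(d)
  list(diff = d,
       mean = colMeans(d),
       sem = apply(d, 2, stats::sd) / sqrt(n),
       time = time)
}

#' Split a continuous pupil recording into baseline and trial windows
#'
#' Uses per-trial trigger codes to cut the continuous recording into a
#' 1.5 s (or trigger-defined) baseline window and a trial window running
#' from encoding onset through the sample immediately before probe onset.
#' Trials missing any required trigger are excluded with a logged reason.
#'
#' @param recording list with `samples`, `time`, `rate` (a continuous
#'   recording) or a `pupil_trace`.
#' @param triggers data frame with columns `time`, `code`, `trial`.
#' @param codes named list giving the codes for `baseline_start`,
#'   `encoding_start`, `probe_onset`.
#' @return List with `trials` (each a list of `baseline` and `trial`
#'   numeric vectors plus `trial_id`) and `exclusions` (data frame of
#'   trial, reason).
#' @export
segment_trials <- function(recording, triggers,
                           codes = list(baseline_start = 1,
                                        encoding_start = 2,
                                        probe_onset = 3)) {
  x <- recording$samples
  time <- recording$time
  out <- list()
  excl <- data.frame(trial = integer(0), reason = character(0))
  for (tr in sort(unique(triggers$trial))) {
    tt <- triggers[triggers$trial == tr, ]
    get1 <- function(code) {
      hit <- tt$time[tt$code == code]
      if (length(hit) == 1) hit else NA_real_
    }
    b0 <- get1(codes$baseline_start)
    e0 <- get1(codes$encoding_start)
    p0 <- get1(codes$probe_onset)
    if (anyNA(c(b0, e0, p0))) {
      missing_code <- c("baseline_start", "encoding_start",
                        "probe_onset")[which(is.na(c(b0, e0, p0)))]
      excl <- rbind(excl, data.frame(
        trial = tr, reason = paste("missing trigger:",
                                   paste(missing_code, collapse = ", "))))
      next
    }
    bwin <- which(time >= b0 & time < e0)
    twin <- which(time >= e0 & time < p0)   # ends 1 sample before probe onset
    out[[length(out) + 1]] <- list(trial_id = tr, baseline = x[bwin],
                                   trial = x[twin],
                                   baseline_time = time[bwin],
                                   trial_time = time[twin])
  }
  list(trials = out, exclusions = excl)
}
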
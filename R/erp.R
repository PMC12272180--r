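#' Preprocess a continuous EEG recording for ERP analysis
#'
#' Downsamples to the analysis rate (with FIR anti-aliasing), re-references
#' every channel to the average of the two mastoids, and applies a
#' zero-phase band-pass FIR filter (default 0.5-20 Hz). The filter is a
#' linear-phase windowed-sinc design applied by centered convolution on a
#' reflection-padded signal, so no group delay or edge transient is
#' introduced; the default transition width is 0.5 Hz (order ~ 3.3 * rate /
#' transition, forced odd-length).
#'
#' @param recording an `eeg_recording`.
#' @param target_rate analysis sampling rate, Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param transition_width filter transition width, Hz.
#' @param mastoids labels of the two reference channels.
#' @return The preprocessed `eeg_recording` (mastoid channels retained,
#'   near-zero after re-referencing).
#' @export
preprocess_eeg <- function(recording, target_rate = 256, band = c(0.5, 20),
                           transition_width = 0.5,
                           mastoids = c("M1", "M2")) {
  if (!all(mastoids %in% recording$channels))
    stop("mastoid channels missing; cannot re-reference")
  X <- recording$samples
  rate <- recording$rate

  if (rate > target_rate) {
    q <- rate / target_rate
    if (abs(q - round(q)) > 1e-9)
      stop("input rate must be an integer multiple of target_rate")
    q <- as.integer(round(q))
    X <- t(apply(X, 1, function(x) signal::decimate(x, q, ftype = "fir")))
    keep <- seq(1, length(recording$time), by = q)[seq_len(ncol(X))]
    recording$time <- recording$time[keep]
    rate <- target_rate
  }

  ref <- colMeans(X[mastoids, , drop = FALSE])
  X <- sweep(X, 2, ref)

  b <- bandpass_fir(band, rate, transition_width)
  X <- t(apply(X, 1, function(x) filter_zerophase(x, b)))

  recording$samples <- X
  recording$rate <- rate
  recording
}

# linear-phase windowed-sinc band-pass (odd length, Type I)
bandpass_fir <- function(band, rate, transition_width) {
  ord <- ceiling(3.3 * rate / transition_width)
  if (ord %% 2 == 1) ord <- ord + 1   # even order -> odd taps
  signal::fir1(ord, band / (rate / 2), type = "pass")
}

# centered (zero-phase) convolution with a symmetric FIR, reflection padding
filter_zerophase <- function(x, b) {
  L <- (length(b) - 1) / 2
  n <- length(x)
  if (L >= n) stop("signal shorter than half the filter length")
  xp <- c(rev(x[seq_len(L)]), x, rev(x[(n - L + 1):n]))
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(L + 1):(L + n)])
}

#' Epoch a recording around stimulus events and reject artifacts
#'
#' Cuts fixed `[-100, 500]` ms epochs around each event, rejects any epoch
#' in which some channel's peak-to-peak range strictly exceeds the
#' threshold (default 100 uV), and baseline-corrects surviving epochs by
#' subtracting each channel's mean over the `[-100, 0)` ms window. Events
#' too close to the recording edges are skipped and logged.
#'
#' @param recording a preprocessed `eeg_recording`.
#' @param events data frame with at least a `time` column (s); extra
#'   columns (`phase`, `position`, `code`) are carried into the report.
#'   Defaults to the recording's triggers.
#' @param window epoch window, s relative to event onset.
#' @param threshold peak-to-peak rejection threshold, uV.
#' @return List of class `eeg_epochs`: `data` (channels x samples x kept
#'   epochs), `time` (s), `channels`, `info` (all events with `kept`,
#'   `reason`), `n_rejected`.
#' @export
epoch_and_reject <- function(recording, events = recording$triggers,
                             window = c(-0.1, 0.5), threshold = 100) {
  rate <- recording$rate
  rel <- seq(round(window[1] * rate), round(window[2] * rate)) / rate
  nt <- length(rel)
  info <- events
  info$kept <- FALSE
  info$reason <- ""
  kept_list <- list()
  for (i in seq_len(nrow(events))) {
    i0 <- which.min(abs(recording$time - events$time[i]))
    idx <- i0 + seq(round(window[1] * rate), round(window[2] * rate))
    if (min(idx) < 1 || max(idx) > ncol(recording$samples)) {
      info$reason[i] <- "event too close to recording edge"
      next
    }
    ep <- recording$samples[, idx, drop = FALSE]
    p2p <- apply(ep, 1, function(ch) max(ch) - min(ch))
    if (any(p2p > threshold)) {
      info$reason[i] <- sprintf("peak-to-peak %.1f uV exceeds threshold", max(p2p))
      next
    }
    bl <- rel < 0
    ep <- ep - rowMeans(ep[, bl, drop = FALSE])
    info$kept[i] <- TRUE
    kept_list[[length(kept_list) + 1]] <- ep
  }
  data <- if (length(kept_list))
    array(unlist(kept_list),
          dim = c(nrow(recording$samples), nt, length(kept_list)),
          dimnames = list(recording$channels, NULL, NULL))
  else array(numeric(0), dim = c(nrow(recording$samples), nt, 0))
  structure(list(data = data, time = rel, channels = recording$channels,
                 info = info, n_rejected = sum(!info$kept & info$reason != "")),
            class = "eeg_epochs")
}

#' Average epochs within groups
#'
#' Means the kept epochs of one participant within groups defined by event
#' metadata columns (e.g. phase and sequence position).
#'
#' @param epochs an `eeg_epochs` (possibly concatenated across trials via
#'   [bind_epochs()]).
#' @param by character vector of `info` columns defining the groups.
#' @return Named list of channels x time matrices, one per group key.
#' @export
average_epochs <- function(epochs, by = c("phase", "position")) {
  kept <- epochs$info[epochs$info$kept, , drop = FALSE]
  if (nrow(kept) != dim(epochs$data)[3])
    stop("epoch data and kept info out of sync")
  keys <- do.call(paste, c(kept[by], sep = "."))
  out <- list()
  for (k in unique(keys)) {
    sel <- which(keys == k)
    out[[k]] <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Concatenate epoch sets from multiple trials
#'
#' @param epoch_list list of `eeg_epochs` sharing channels and time base.
#' @return A single `eeg_epochs`.
#' @export
bind_epochs <- function(epoch_list) {
  stopifnot(length(epoch_list) > 0)
  datas <- lapply(epoch_list, `[[`, "data")
  infos <- lapply(epoch_list, `[[`, "info")
  data <- array(unlist(datas),
                dim = c(dim(datas[[1]])[1], dim(datas[[1]])[2],
                        sum(vapply(datas, function(d) dim(d)[3], numeric(1)))),
                dimnames = list(epoch_list[[1]]$channels, NULL, NULL))
  structure(list(data = data, time = epoch_list[[1]]$time,
                 channels = epoch_list[[1]]$channels,
                 info = do.call(rbind, infos),
                 n_rejected = sum(vapply(epoch_list, `[[`, numeric(1),
                                         "n_rejected"))),
            class = "eeg_epochs")
}

#' Grand average across participants
#'
#' Averages participant-level ERPs (channels x time matrices, e.g. from
#' [average_epochs()]) across participants, per group key. Groups absent
#' for some participants are averaged over the participants that have them.
#'
#' @param participant_erps list over participants, each a named list of
#'   channels x time matrices.
#' @return Named list of grand-average matrices with attribute `n` (number
#'   of participants contributing).
#' @export
grand_average <- function(participant_erps) {
  keys <- unique(unlist(lapply(participant_erps, names)))
  out <- list()
  for (k in keys) {
    mats <- Filter(Negate(is.null), lapply(participant_erps, `[[`, k))
    g <- Reduce(`+`, mats) / length(mats)
    attr(g, "n") <- length(mats)
    out[[k]] <- g
  }
  out
}

#' Extract the P2 amplitude from an ERP
#'
#' Mean ERP amplitude over the 190-220 ms post-stimulus window and the
#' fronto-central channel cluster (Fz, FCz, Cz, FC1, FC2). The window is
#' fixed in absolute time, not peak-locked.
#'
#' @param erp channels x time matrix with channel dimnames.
#' @param time time vector (s) for the columns.
#' @param channels cluster channels to average.
#' @param window measurement window, s (closed interval).
#' @return Scalar amplitude, uV.
#' @export
extract_p2 <- function(erp, time,
                       channels = c("Fz", "FCz", "Cz", "FC1", "FC2"),
                       window = c(0.190, 0.220)) {
  missing <- setdiff(channels, rownames(erp))
  if (length(missing)) stop("cluster channels missing: ",
                            paste(missing, collapse = ", "))
  idx <- which(time >= window[1] & time <= window[2])
  if (!length(idx)) stop("measurement window outside epoch")
  mean(erp[channels, idx])
}

#' Repeated-measures ANOVA on a within-participant factorial table
#'
#' Fits the fully-within repeated-measures ANOVA with one error stratum per
#' within-participant term (participant x term interactions), as used for
#' the three-way analysis of P2 amplitudes with factors working-memory
#' modality, working-memory domain and intervening-task domain. Reports F,
#' degrees of freedom and p per main effect and interaction together with
#' classical and generalized eta-squared effect sizes.
#'
#' @param table data frame with the dependent variable, a participant id
#'   column and the factor columns; one observation per participant x cell
#'   (replicates are averaged first).
#' @param dv,id names of the dependent-variable and participant columns.
#' @param factors names of the within-participant factors.
#' @return Data frame of class `rm_anova`: one row per term with `df1`,
#'   `df2`, `F`, `p`, `eta_sq`, `eta_sq_gen`.
#' @export
rm_anova <- function(table, dv = "amplitude", id = "participant",
                     factors = c("wm_modality", "wm_domain", "intervening")) {
  miss <- setdiff(c(dv, id, factors), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(table[[dv]],
                          by = c(list(.id = factor(table[[id]])),
                                 lapply(table[factors], factor)),
                          FUN = mean)
  names(agg) <- c(".id", factors, ".y")
  n_cells <- prod(vapply(agg[factors], nlevels, integer(1)))
  counts <- table(agg$.id)
  if (any(counts != n_cells))
    stop("design not fully crossed within participants (missing cells)")

  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.id/(", rhs, "))"))
  fit <- stats::aov(form, data = agg)
  s <- summary(fit)

  rows <- list()
  ss_resid_total <- 0
  ss_subject <- 0
  ss_all <- 0
  for (stratum in s) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    ss_all <- ss_all + sum(tab[["Sum Sq"]])
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") {
        if (all(terms == "Residuals")) ss_subject <- tab[["Sum Sq"]][i]
        else ss_resid_total <- ss_resid_total + tab[["Sum Sq"]][i]
        next
      }
      resid_row <- which(terms == "Residuals")
      rows[[terms[i]]] <- data.frame(
        term = terms[i],
        df1 = tab[["Df"]][i],
        df2 = tab[["Df"]][resid_row],
        ss = tab[["Sum Sq"]][i],
        ss_err = tab[["Sum Sq"]][resid_row],
        F = tab[["F value"]][i],
        p = tab[["Pr(>F)"]][i])
    }
  }
  out <- do.call(rbind, rows)
  # a term with zero effect variance is a zero effect, not 0/0
  degenerate <- out$ss < 1e-12
  out$F[degenerate] <- 0
  out$p[degenerate] <- 1
  out$eta_sq <- out$ss / ss_all
  out$eta_sq_gen <- out$ss / (out$ss + ss_subject + ss_resid_total)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA\n")
  show <- x[, c("term", "df1", "df2", "F", "p", "eta_sq", "eta_sq_gen")]
  print.data.frame(format(show, digits = digits), row.names = FALSE)
  invisible(x)
}
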
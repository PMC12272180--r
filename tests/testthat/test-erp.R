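test_that("the band-pass filter meets its frequency-response specification", {
  rate <- 256
  t <- (0:4095) / rate
  b <- dualtaskr:::bandpass_fir(c(0.5, 20), rate, 0.5)
  mid <- 1500:2500
  gain <- function(f) {
    s <- sin(2 * pi * f * t)
    stats::sd(dualtaskr:::filter_zerophase(s, b)[mid]) / stats::sd(s[mid])
  }
  expect_equal(gain(10), 1, tolerance = 0.05)          # passband
  expect_lt(20 * log10(gain(40)), -20)                 # stopband
  dc <- dualtaskr:::filter_zerophase(rep(5, 4096), b)  # steady state at 0 Hz
  expect_lt(max(abs(dc[mid])) / 5, 0.05)
})

test_that("zero-phase filtering preserves the symmetry center of a pulse", {
  rate <- 256
  n <- 4097                                  # odd: exact center sample
  x <- exp(-((seq_len(n)) - 2049)^2 / 300)
  b <- dualtaskr:::bandpass_fir(c(0.5, 20), rate, 0.5)
  y <- dualtaskr:::filter_zerophase(x, b)
  expect_equal(y, rev(y), tolerance = 1e-6)
})

test_that("preprocessing requires mastoids and removes the reference signal", {
  d <- cell_design("auditory", "spatial", "none", n_trials = 1, seed = 61)
  rec <- simulate_eeg_trial(d[1, ], eeg_model(artifact_rate = 0), seed = 61)
  pp <- preprocess_eeg(rec)
  expect_equal(pp$rate, 256)
  expect_equal(dim(pp$samples), dim(rec$samples))
  bad <- rec
  bad$channels <- setdiff(rec$channels, "M1")
  bad$samples <- rec$samples[bad$channels, ]
  expect_error(preprocess_eeg(bad), "mastoid")
})

test_that("the 2048 Hz acquisition mode downsamples to 256 Hz", {
  d <- cell_design("auditory", "spatial", "none", n_trials = 1, seed = 62)
  em <- eeg_model(pink_noise_sd = 1, alpha_amp = 0, artifact_rate = 0)
  rec <- simulate_eeg_trial(d[1, ], em, rate = 2048, seed = 62)
  pp <- preprocess_eeg(rec, target_rate = 256)
  expect_equal(pp$rate, 256)
  expect_equal(ncol(pp$samples), length(pp$time))
  expect_lt(abs(ncol(pp$samples) - ncol(rec$samples) / 8), 2)
})

test_that("peak-to-peak rejection is strict at the 100 uV boundary", {
  rate <- 256
  time <- seq(-1, 2, by = 1 / rate)
  X <- matrix(0, 3, length(time),
              dimnames = list(c("A", "B", "C"), NULL))
  rec <- structure(list(samples = X, channels = rownames(X), rate = rate,
                        time = time,
                        triggers = data.frame(time = c(0, 1))),
                   class = "eeg_recording")
  # epoch 1: 99 uV peak-to-peak on one channel -> kept
  idx1 <- which(time > 0.1 & time < 0.3)
  rec$samples["B", idx1[1]] <- 99
  # epoch 2: 101 uV -> rejected
  idx2 <- which(time > 1.1 & time < 1.3)
  rec$samples["C", idx2[1]] <- 101
  ep <- epoch_and_reject(rec, data.frame(time = c(0, 1)))
  expect_equal(ep$info$kept, c(TRUE, FALSE))
  expect_match(ep$info$reason[2], "exceeds threshold")
})

test_that("baseline correction zeroes the pre-stimulus mean per channel", {
  d <- cell_design("auditory", "spatial", "AT", n_trials = 1, seed = 63)
  rec <- simulate_eeg_trial(d[1, ], eeg_model(artifact_rate = 0), seed = 63)
  ep <- epoch_and_reject(rec)
  bl <- ep$time < 0
  for (k in seq_len(dim(ep$data)[3])) {
    expect_lt(max(abs(rowMeans(ep$data[, bl, k]))), 1e-10)
  }
  # events hanging over the recording edge are skipped with a log entry
  ev <- data.frame(time = min(rec$time) + 0.01)
  ep2 <- epoch_and_reject(rec, ev)
  expect_false(any(ep2$info$kept))
  expect_match(ep2$info$reason[1], "edge")
})

test_that("rejected fraction tracks the generator's artifact rate", {
  d <- cell_design("auditory", "spatial", "AT", n_trials = 10, seed = 64)
  em <- eeg_model(artifact_rate = 0.15, pink_noise_sd = 3)
  total <- kept <- 0
  for (r in 1:8) {
    for (i in 1:10) {
      rec <- simulate_eeg_trial(d[i, ], em, seed = 100 * r + i)
      ep <- epoch_and_reject(rec)
      total <- total + nrow(ep$info)
      kept <- kept + sum(ep$info$kept)
    }
  }
  # 880 epochs; artifact bursts can clip the neighbouring epoch too
  expect_equal(1 - kept / total, 0.15, tolerance = 0.35)
})

test_that("noise-free epochs reproduce the inserted template superposition", {
  # onsets on the 256 Hz sample grid so extraction is phase-exact
  mk_seq <- function() structure(
    list(onsets = c(0, 0.375, 0.75, 1.125), locations = c(0, 0, 0, 0),
         intervals = rep("long", 3), interval_ms = rep(325, 3),
         offset = 1.175), class = "stimulus_sequence")
  trial <- list(wm_modality = "auditory", wm_domain = "spatial",
                intervening = "none", encoding_seq = mk_seq(),
                probe_seq = mk_seq(), intervening_seq = NULL)
  em <- eeg_model(pink_noise_sd = 0, alpha_amp = 0, artifact_rate = 0)
  rec <- simulate_eeg_trial(trial, em, seed = 65)
  ep <- epoch_and_reject(rec)           # raw epoching, no filtering
  av <- average_epochs(ep, by = c("phase", "position"))
  # interior encoding events share an identical neighbourhood
  expect_equal(av[["encoding.2"]], av[["encoding.3"]], tolerance = 1e-10)
  # direct superposition oracle for the second encoding stimulus
  comps <- default_erp_components()
  shifts <- c(-0.75, -0.375, 0, 0.375, 0.75)   # neighbours in epoch reach
  tpl <- rowSums(vapply(shifts, function(s)
    dualtaskr:::erp_template(ep$time - s, comps), numeric(length(ep$time))))
  w <- dualtaskr:::topo_weights(rec$channels, "erp")
  expected <- outer(w, tpl)
  expected <- expected - rowMeans(expected[, ep$time < 0, drop = FALSE])
  expect_equal(av[["encoding.2"]], expected, tolerance = 1e-8,
               ignore_attr = TRUE)
  # single-epoch group: average equals the epoch
  one <- ep$data[, , which(ep$info$phase == "probe" & ep$info$position == 1)]
  expect_equal(av[["probe.1"]], one, tolerance = 1e-12)
})

test_that("grand averaging is the plain arithmetic mean across participants", {
  m1 <- list(a = matrix(1, 2, 3))
  m2 <- list(a = matrix(3, 2, 3), b = matrix(7, 2, 3))
  g <- grand_average(list(m1, m2))
  expect_equal(g$a, matrix(2, 2, 3), ignore_attr = TRUE)
  expect_equal(g$b, matrix(7, 2, 3), ignore_attr = TRUE)  # single contributor
  expect_equal(attr(g$a, "n"), 2)
})

test_that("P2 extraction is a fixed-window fronto-central cluster mean", {
  time <- seq(-0.1, 0.5, by = 1 / 256)
  chans <- c("Fz", "FCz", "Cz", "FC1", "FC2", "Pz")
  erp <- matrix(2, length(chans), length(time), dimnames = list(chans, NULL))
  expect_equal(extract_p2(erp, time), 2)
  # matches an independently computed windowed mean
  set.seed(66)
  erp2 <- matrix(stats::rnorm(length(chans) * length(time)), length(chans),
                 dimnames = list(chans, NULL))
  idx <- which(time >= 0.19 & time <= 0.22)
  oracle <- mean(erp2[c("Fz", "FCz", "Cz", "FC1", "FC2"), idx])
  expect_equal(extract_p2(erp2, time), oracle)
  # the window is absolute: shifting the waveform changes the measurement
  tpl <- dualtaskr:::erp_template(time, default_erp_components())
  erp3 <- matrix(rep(tpl, each = length(chans)), length(chans),
                 dimnames = list(chans, NULL))
  shifted <- matrix(rep(dualtaskr:::erp_template(time - 0.05,
                                                 default_erp_components()),
                        each = length(chans)), length(chans),
                    dimnames = list(chans, NULL))
  expect_false(isTRUE(all.equal(extract_p2(erp3, time),
                                extract_p2(shifted, time))))
  expect_error(extract_p2(erp3[-1, , drop = FALSE], time), "missing")
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 2 x 2 within design, 3 participants: small enough to do by hand
  tab <- expand.grid(participant = 1:3, A = c("a1", "a2"), B = c("b1", "b2"),
                     stringsAsFactors = FALSE)
  tab$amplitude <- c(1, 2, 3,   2, 4, 5,   2, 3, 3,   5, 7, 8)
  res <- rm_anova(tab, dv = "amplitude", factors = c("A", "B"))

  Y <- array(tab$amplitude, dim = c(3, 2, 2))   # participant x A x B
  gm <- mean(Y)
  ssA <- 3 * 2 * sum((apply(Y, 2, mean) - gm)^2)
  ssB <- 3 * 2 * sum((apply(Y, 3, mean) - gm)^2)
  cellAB <- apply(Y, c(2, 3), mean)
  ssAB <- 3 * sum((cellAB - outer(apply(Y, 2, mean), apply(Y, 3, mean), "+") + gm)^2)
  # error strata: participant x effect interactions
  pA <- apply(Y, c(1, 2), mean); pB <- apply(Y, c(1, 3), mean)
  pm <- apply(Y, 1, mean)
  sspA <- 2 * sum(sweep(sweep(pA, 1, pm), 2, apply(Y, 2, mean) - gm) ^ 2)
  sspB <- 2 * sum(sweep(sweep(pB, 1, pm), 2, apply(Y, 3, mean) - gm) ^ 2)
  FA <- (ssA / 1) / (sspA / 2)
  FB <- (ssB / 1) / (sspB / 2)
  expect_equal(res$F[res$term == "A"], FA)
  expect_equal(res$F[res$term == "B"], FB)
  expect_equal(res$ss[res$term == "A:B"], ssAB)
  expect_equal(res$p[res$term == "A"], stats::pf(FA, 1, 2, lower.tail = FALSE))
})

test_that("identical cell values give zero F throughout", {
  tab <- expand.grid(participant = 1:4,
                     wm_modality = c("auditory", "visual"),
                     wm_domain = c("temporal", "spatial"),
                     intervening = c("AT", "AS"), stringsAsFactors = FALSE)
  tab$amplitude <- rep(c(3, 5, 4, 6), times = 8)   # varies only by participant
  res <- rm_anova(tab)
  expect_true(all(abs(res$F) < 1e-10))
  expect_error(rm_anova(tab[-1, ]), "crossed")
})

test_that("an injected modality gain difference is recovered end to end", {
  # raw-EEG route: halved P2 gain in one cell shifts the extracted means
  d1 <- cell_design("auditory", "temporal", "AT", n_trials = 30, seed = 67)
  d2 <- cell_design("visual", "temporal", "AT", n_trials = 30, seed = 67)
  em <- eeg_model(pink_noise_sd = 3, alpha_amp = 2, artifact_rate = 0,
                  p2_gain = c(AT.auditory.temporal = 0.5,
                              AT.visual.temporal = 1.0))
  p2_of <- function(dd, sd_off) {
    eps <- lapply(seq_len(nrow(dd)), function(i) {
      rec <- simulate_eeg_trial(dd[i, ], em, seed = sd_off + i)
      epoch_and_reject(rec, rec$triggers[rec$triggers$phase == "intervening" &
                                           rec$triggers$position == 1, ])
    })
    av <- average_epochs(bind_epochs(eps), by = "phase")
    extract_p2(av$intervening, eps[[1]]$time)
  }
  expect_lt(p2_of(d1, 1000), p2_of(d2, 2000))
})

test_that("the measurement-level P2 generator drives a detectable modality effect", {
  set.seed(68)
  hits <- replicate(10, {
    tab <- simulate_p2_table(n_participants = 20, n_trials = 40)
    a <- rm_anova(tab)
    a$p[a$term == "wm_modality"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
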
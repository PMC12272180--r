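test_that("mirror padding round-trips exactly and reflects the edges", {
  set.seed(71)
  x <- stats::rnorm(2000)
  xp <- mirror_pad(x, pad_s = 2, rate = 256)
  P <- attr(xp, "pad")
  expect_equal(P, 512)
  expect_identical(unpad(xp), x)
  # reflection identity: padded[k] == signal[P - 1 - k] (0-based)
  for (k in 0:10) expect_equal(xp[k + 1], x[P - k])
  # tail reflection
  n <- length(x)
  for (k in 0:10) expect_equal(xp[P + n + k + 1], x[n - k])
  # no jump at the boundary beyond the signal's own first difference scale
  expect_lte(abs(xp[P] - xp[P + 1]), max(abs(diff(x[1:20]))) + 1e-12)
  # short signals fall back to full-length reflection
  expect_message(mirror_pad(stats::rnorm(100), 5, 256), "full-length")
})

test_that("the Morlet transform agrees with direct time-domain convolution", {
  set.seed(72)
  rate <- 256
  x <- stats::rnorm(2 * rate)
  tf <- morlet_tfr(x, rate, freqs = c(4, 10, 23))
  for (f in c(4, 10, 23)) {
    oracle <- morlet_direct_power(x, rate, f)
    expect_lt(max(abs(tf$power[as.character(f), ] - oracle)) / max(oracle),
              1e-6)
  }
})

test_that("the transform is frequency selective with quadratic amplitude scaling", {
  rate <- 256
  t <- (0:2047) / rate
  s <- sin(2 * pi * 10 * t)
  tf1 <- morlet_tfr(s, rate, freqs = c(5, 10))
  mid <- 500:1500
  expect_gt(mean(tf1$power["10", mid]) / mean(tf1$power["5", mid]), 10)
  tf2 <- morlet_tfr(2 * s, rate, freqs = 10)
  expect_equal(mean(tf2$power[1, mid]) / mean(tf1$power["10", mid]), 4,
               tolerance = 1e-9)
  expect_error(morlet_tfr(s, rate, freqs = c(10, 130)), "Nyquist")
})

test_that("dB baselining has the closed-form values and condition invariance", {
  pow <- matrix(c(1, 2, 4, 8), 2)
  base <- c(1, 2)
  db <- db_baseline(pow, base)
  expect_equal(db[1, 1], 0)
  expect_equal(db[1, 2], 10 * log10(4), tolerance = 1e-12)
  expect_equal(db[2, 2], 10 * log10(4), tolerance = 1e-12)
  expect_equal(db_baseline(2 * pow, 2 * base), db)   # common scale cancels
  expect_error(db_baseline(pow, c(0, 1)), "positive")
  expect_error(db_baseline(pow, 1), "per frequency")
})

test_that("ERP subtraction removes evoked copies and spares oscillations", {
  rate <- 256
  time <- seq(-0.5, 2, by = 1 / rate)
  chans <- c("Cz", "Pz")
  tpl_t <- seq(-0.1, 0.5, by = 1 / rate)
  tpl <- rbind(Cz = exp(-(tpl_t - 0.2)^2 / 0.002),
               Pz = 0.5 * exp(-(tpl_t - 0.2)^2 / 0.002))
  X <- matrix(0, 2, length(time), dimnames = list(chans, NULL))
  ev <- data.frame(time = c(0, 1), phase = "encoding", position = 1:2)
  for (i in 1:2) {
    idx <- which.min(abs(time - ev$time[i])) + round(tpl_t * rate)
    X[, idx] <- X[, idx] + tpl
  }
  rec <- structure(list(samples = X, channels = chans, rate = rate,
                        time = time, triggers = ev),
                   class = "eeg_recording")
  bank <- list(encoding.1 = list(erp = tpl, time = tpl_t),
               encoding.2 = list(erp = tpl, time = tpl_t))
  out <- subtract_erp(rec, bank)
  expect_lt(max(abs(out$samples)), 1e-10)
  # a pure oscillation with no bank match for its events is untouched
  osc <- matrix(rep(sin(2 * pi * 10 * time), each = 2), 2,
                dimnames = list(chans, NULL))
  rec2 <- structure(list(samples = osc, channels = chans, rate = rate,
                         time = time,
                         triggers = data.frame(time = 0.5, phase = "probe",
                                               position = 1)),
                    class = "eeg_recording")
  expect_warning(out2 <- subtract_erp(rec2, bank), "no ERP bank entry")
  expect_identical(out2$samples, osc)
  # subtraction reduces wavelet power at the evoked component's scale
  noisy <- rec
  noisy$samples <- X + osc
  sub <- subtract_erp(noisy, bank)
  pow_before <- mean(morlet_tfr(noisy$samples["Cz", ], rate, 6)$power)
  pow_after <- mean(morlet_tfr(sub$samples["Cz", ], rate, 6)$power)
  expect_lt(pow_after, pow_before)
})

test_that("individual alpha frequency follows the absolute-change rule", {
  freqs <- 4:16
  time <- seq(-1.5, 6, by = 1 / 128)
  mk_map <- function(f, sign = 1) {
    db <- matrix(0, length(freqs), length(time))
    ret <- time >= 0 & time < 5.5
    db[match(f, freqs), ret] <- sign * 3
    db[match(f, freqs) + c(-1, 1), ret] <- sign * 1.5
    db
  }
  ia <- individual_alpha(mk_map(10), time, freqs = freqs)
  expect_equal(ia$iaf, 10)
  # suppression (negative change) selects the same frequency
  ia2 <- individual_alpha(mk_map(10, sign = -1), time, freqs = freqs)
  expect_equal(ia2$iaf, 10)
  # flat spectrum: tie broken toward the lower band edge
  flat <- matrix(1, length(freqs), length(time))
  expect_equal(individual_alpha(flat, time, freqs = freqs)$iaf, 8)
  # time course averages iaf - 1, iaf, iaf + 1
  expect_equal(max(ia$timecourse), (3 + 1.5 + 1.5) / 3)
  expect_error(individual_alpha(mk_map(10)[1:3, ], time, freqs = 4:6),
               "outside")
})

test_that("samples within 500 ms of the retention edges never influence the IAF", {
  freqs <- 7:13
  time <- seq(-1, 6, by = 1 / 128)
  db <- matrix(0, length(freqs), length(time))
  # huge change at 12 Hz only inside the trimmed-away margins
  margin <- (time >= 0 & time < 0.5) | (time >= 5.0 & time < 5.5)
  db[match(12, freqs), margin] <- 50
  core <- time >= 0.5 & time < 5.0
  db[match(9, freqs), core] <- 2
  ia <- individual_alpha(db, time, freqs = freqs)
  expect_equal(ia$iaf, 9)
})

test_that("injected alpha frequencies are recovered from simulated EEG", {
  d <- cell_design("auditory", "spatial", "none", n_trials = 10, seed = 73)
  ok <- 0
  for (f in c(8, 10, 12)) {
    em <- eeg_model(artifact_rate = 0,
                    alpha_frequencies = stats::setNames(f, "1"))
    pows <- 0
    for (k in 1:10) {
      rec <- simulate_eeg_trial(d[k, ], em, participant = 1,
                                seed = 100 * f + k)
      xp <- mirror_pad(rec$samples["Pz", ], 5, rec$rate)
      pows <- pows + morlet_tfr(xp, rec$rate, freqs = 4:16)$power / 10
    }
    blpow <- rowMeans(pows[, rec$time < min(rec$time) + 1.5])
    db <- db_baseline(pows, blpow)
    ia <- individual_alpha(db, rec$time, freqs = 4:16)
    ok <- ok + (ia$iaf == f)
  }
  expect_equal(ok, 3)
})

test_that("alpha contrasts flag injected suppression only in its window", {
  set.seed(74)
  time <- seq(0, 5.5, by = 1 / 64)
  n <- 14
  mk <- function(shift_window = NULL, delta = -1.5) {
    m <- matrix(stats::rnorm(n * length(time), sd = 0.5), n)
    if (!is.null(shift_window))
      m[, time >= shift_window[1] & time < shift_window[2]] <-
        m[, time >= shift_window[1] & time < shift_window[2]] + delta
    m
  }
  tc <- list(none = mk(), AT = mk(c(2, 3.5)))
  res <- alpha_contrasts(tc, time, n_iter = 400, seed = 75)
  during <- res$none_vs_AT[["2-3.5s"]]
  after <- res$none_vs_AT[["3.5-5s"]]
  expect_gt(mean(during$significant), 0.5)
  expect_lt(mean(after$significant), 0.2)
  # identical inputs: zero observed t everywhere
  res0 <- alpha_contrasts(list(a = tc$none, b = tc$none), time,
                          n_iter = 100, seed = 76)
  expect_true(all(res0$a_vs_b[["2-3.5s"]]$t_observed == 0))
})
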
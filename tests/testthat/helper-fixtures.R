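# Shared fixtures, built in code at test time.

small_config <- function(n = 2, seed = 1L)
  experiment_config(n_participants = n, seed = seed)

# a stimuli-filled design restricted to one condition cell
cell_design <- function(modality = "auditory", domain = "spatial",
                        intervening = "none", n_trials = 6, seed = 1L,
                        n_participants = 1) {
  d <- generate_design(experiment_config(n_participants = n_participants,
                                         seed = seed))
  d <- d[d$wm_modality == modality & d$wm_domain == domain &
           d$intervening == intervening, , drop = FALSE]
  generate_stimuli(utils::head(d, n_trials), seed = seed)
}

# direct time-domain Morlet convolution, the independent oracle for the
# FFT-based transform
morlet_direct_power <- function(x, rate, f, width = 5) {
  w <- dualtaskr:::morlet_wavelet(f, rate, width)
  m <- length(w)
  h <- (m - 1) / 2
  n <- length(x)
  wr <- rev(w)   # convolution flips the kernel
  vapply(seq_len(n), function(i) {
    idx <- (i - h):(i + h)
    ok <- idx >= 1 & idx <= n
    Mod(sum(x[idx[ok]] * wr[ok]))^2
  }, numeric(1))
}

# independent run-length scanner (simple loop, no rle)
scan_runs <- function(flags, min_run) {
  out <- NULL
  i <- 1
  n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out <- rbind(out, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}
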
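#' Generate a blocked dual-task condition design
#'
#' Builds the per-participant block schedule for the 2 (working-memory
#' modality) x 2 (working-memory domain) x 3 (intervening condition:
#' none / auditory-temporal / auditory-spatial) design. Trials are grouped
#' into blocks that hold one condition cell constant; each block contains an
#' equal number of same and different trials in random order; every cell
#' appears once per cycle before any cell repeats; the same cell never
#' occupies two adjacent blocks; and auditory and visual working-memory
#' cells are scheduled into separate sessions.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed; defaults to the config seed.
#' @return A data frame of class `trial_table`, one row per trial, with
#'   columns `participant`, `session`, `block`, `wm_modality`, `wm_domain`,
#'   `intervening`, `trial`, `trial_type`. Stimulus and response columns are
#'   added by [generate_stimuli()] and [simulate_behavior()].
#' @seealso [generate_stimuli()], [simulate_behavior()]
#' @export
generate_design <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$trials_per_block %% 2 != 0)
    stop("trials_per_block must be even")
  n_cycles <- config$trials_per_combination %/% config$trials_per_block

  cells <- expand.grid(wm_domain = config$wm_domains,
                       intervening = config$intervening_conditions,
                       stringsAsFactors = FALSE)

  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    with_seed(derive_seed(seed, "design", p), {
      modal_order <- sample(config$wm_modalities)
      sessions <- lapply(seq_along(modal_order), function(s) {
        sched <- schedule_blocks(nrow(cells), n_cycles)
        data.frame(
          session = s,
          wm_modality = modal_order[s],
          wm_domain = cells$wm_domain[sched],
          intervening = cells$intervening[sched],
          stringsAsFactors = FALSE
        )
      })
      blocks <- do.call(rbind, sessions)
      blocks$block <- seq_len(nrow(blocks))
      trials <- blocks[rep(seq_len(nrow(blocks)), each = config$trials_per_block), ]
      trials$trial <- rep(seq_len(config$trials_per_block), times = nrow(blocks))
      half <- config$trials_per_block / 2
      trials$trial_type <- unlist(lapply(seq_len(nrow(blocks)), function(b)
        sample(rep(c("same", "different"), each = half))))
      trials$participant <- p
      out[[p]] <- trials
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("participant", "session", "block", "wm_modality",
                 "wm_domain", "intervening", "trial", "trial_type")]
  class(res) <- c("trial_table", "data.frame")
  attr(res, "config") <- config
  res
}

# Cycle-structured block order over n_cells cells: each cycle is a random
# permutation; adjacent blocks (including across cycle boundaries) never
# share a cell. Resampling is bounded to keep pathological inputs from
# looping forever (with >= 2 cells a valid permutation always exists).
schedule_blocks <- function(n_cells, n_cycles, max_attempts = 1000L) {
  if (n_cells < 2 && n_cycles > 1)
    stop("adjacency constraint impossible with a single condition cell")
  sched <- integer(0)
  for (cyc in seq_len(n_cycles)) {
    for (attempt in seq_len(max_attempts)) {
      perm <- sample.int(n_cells)
      if (length(sched) == 0 || perm[1] != sched[length(sched)]) {
        sched <- c(sched, perm)
        break
      }
      if (attempt == max_attempts)
        stop("could not satisfy block adjacency constraint")
    }
  }
  sched
}

# Interval sets (ms) per working-memory modality; the visual set is wider so
# short/long intervals are equally discriminable across modalities.
wm_interval_ms <- function(modality) {
  switch(modality,
         auditory = c(short = 200, long = 340),
         visual   = c(short = 200, long = 580),
         stop("unknown modality: ", modality))
}

STIM_DUR_S <- 0.05  # every stimulus (chord, noise burst, patch jitter) lasts 50 ms
AUD_AZIMUTHS <- c(-90, -45, 0, 45, 90)
N_VISUAL_POSITIONS <- 12L

seq_onsets <- function(interval_ms) {
  c(0, cumsum(STIM_DUR_S + interval_ms / 1000))
}

#' Generate encoding and probe sequences for one working-memory trial
#'
#' Each sequence holds four stimuli and three inter-stimulus intervals drawn
#' from the modality's short/long set (auditory 200/340 ms, visual
#' 200/580 ms). The first stimulus position is fixed (central loudspeaker or
#' top-center patch) so that both domains carry three items to remember. On
#' "different" trials the probe differs from the encoding sequence in the
#' attended domain; on "same" trials the attended domain is identical. The
#' unattended domain changes with probability `unattended_change_prob`,
#' except in the auditory-spatial condition, where both sequences are
#' isochronous at the long interval.
#'
#' @param wm_modality "auditory" or "visual".
#' @param wm_domain "temporal" or "spatial" (the attended domain).
#' @param trial_type "same" or "different".
#' @param unattended_change_prob probability that the unattended domain
#'   changes between encoding and probe.
#' @return A list with elements `encoding` and `probe`, each a
#'   `stimulus_sequence`: `onsets` (s from sequence start), `locations`
#'   (azimuth degrees or circular position index), `intervals`
#'   (short/long labels), `interval_ms`, and `offset` (s, end of the final
#'   stimulus).
#' @export
generate_wm_sequences <- function(wm_modality, wm_domain, trial_type,
                                  unattended_change_prob = 0.5) {
  iv <- wm_interval_ms(wm_modality)
  isochronous <- wm_modality == "auditory" && wm_domain == "spatial"

  draw_labels <- function() sample(c("short", "long"), 3, replace = TRUE)
  draw_locations <- function() {
    if (wm_modality == "auditory") c(0, sample(AUD_AZIMUTHS, 3, replace = TRUE))
    else c(1L, sample.int(N_VISUAL_POSITIONS, 3, replace = TRUE))
  }

  enc_labels <- if (isochronous) rep("long", 3) else draw_labels()
  enc_locs <- draw_locations()

  if (wm_domain == "temporal") {
    probe_labels <- if (trial_type == "same") enc_labels else {
      repeat {
        cand <- draw_labels()
        if (!identical(cand, enc_labels)) break
      }
      cand
    }
    probe_locs <- if (stats::runif(1) < unattended_change_prob)
      draw_locations() else enc_locs
  } else {
    probe_locs <- if (trial_type == "same") enc_locs else {
      repeat {
        cand <- draw_locations()
        if (!identical(cand[-1], enc_locs[-1])) break
      }
      cand
    }
    probe_labels <- if (isochronous) enc_labels else {
      if (stats::runif(1) < unattended_change_prob) draw_labels() else enc_labels
    }
  }

  mk <- function(labels, locs) {
    ms <- unname(iv[labels])
    structure(list(onsets = seq_onsets(ms)[1:4],
                   locations = locs,
                   intervals = labels,
                   interval_ms = ms,
                   offset = seq_onsets(ms)[4] + STIM_DUR_S),
              class = "stimulus_sequence")
  }
  list(encoding = mk(enc_labels, enc_locs), probe = mk(probe_labels, probe_locs))
}

#' Generate one intervening-task stimulus sequence
#'
#' Three white-noise bursts presented from two near-frontal loudspeakers
#' (azimuths -4 and 0 degrees) in an A-B-A location pattern. One of the two
#' inter-stimulus intervals, chosen at random, is longer: interval durations
#' are jittered uniformly by +/-60 ms around means of 370 ms (short) and
#' 550 ms (long), giving a 180 ms expected difference with non-overlapping
#' ranges. The temporal variant asks which interval was longer; the spatial
#' variant asks whether the middle sound was left or right of the flankers.
#'
#' @param condition "AT" (temporal judgment) or "AS" (spatial judgment).
#' @param jitter_ms half-width of the uniform jitter applied independently
#'   to each interval, in ms.
#' @return An `intervening_sequence` list: `onsets` (s from sequence start),
#'   `interval_ms` (length 2), `longer_interval` ("first"/"second"),
#'   `locations` (azimuths, A-B-A), `middle_side` ("left"/"right"),
#'   `correct_answer` (the response that scores correct under `condition`).
#' @export
generate_intervening_sequence <- function(condition = c("AT", "AS"),
                                          jitter_ms = 60) {
  condition <- match.arg(condition)
  short_ms <- stats::runif(1, 370 - jitter_ms, 370 + jitter_ms)
  long_ms <- stats::runif(1, 550 - jitter_ms, 550 + jitter_ms)
  longer_first <- stats::runif(1) < 0.5
  intervals <- if (longer_first) c(long_ms, short_ms) else c(short_ms, long_ms)
  first_loc <- sample(c(-4, 0), 1)
  middle_loc <- if (first_loc == 0) -4 else 0
  locations <- c(first_loc, middle_loc, first_loc)
  middle_side <- if (middle_loc < first_loc) "left" else "right"
  longer_interval <- if (longer_first) "first" else "second"
  structure(list(
    onsets = seq_onsets(intervals)[1:3],
    interval_ms = intervals,
    longer_interval = longer_interval,
    locations = locations,
    middle_side = middle_side,
    correct_answer = if (condition == "AT") longer_interval else middle_side
  ), class = "intervening_sequence")
}

#' Attach stimulus sequences to a design
#'
#' Fills the encoding, probe and (where present) intervening sequences for
#' every trial of a design produced by [generate_design()], reproducibly
#' from the seed.
#'
#' @param design a `trial_table` from [generate_design()].
#' @param seed integer seed; defaults to the design config's seed.
#' @param unattended_change_prob passed to [generate_wm_sequences()].
#' @return The design with list-columns `encoding_seq`, `probe_seq`,
#'   `intervening_seq` (`NULL` entries where no intervening task is run).
#' @export
generate_stimuli <- function(design, seed = NULL,
                             unattended_change_prob = 0.5) {
  cfg <- attr(design, "config")
  if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$seed else 1L
  n <- nrow(design)
  enc <- probe <- intv <- vector("list", n)
  with_seed(derive_seed(seed, "stimuli"), {
    for (i in seq_len(n)) {
      sq <- generate_wm_sequences(design$wm_modality[i], design$wm_domain[i],
                                  design$trial_type[i], unattended_change_prob)
      enc[[i]] <- sq$encoding
      probe[[i]] <- sq$probe
      if (design$intervening[i] != "none")
        intv[[i]] <- generate_intervening_sequence(design$intervening[i])
    }
  })
  design[["encoding_seq"]] <- I(enc)
  design[["probe_seq"]] <- I(probe)
  design[["intervening_seq"]] <- I(intv)
  design
}
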
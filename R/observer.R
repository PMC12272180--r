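#' Behavioral observer model
#'
#' A logistic observer whose per-trial error probability is determined by a
#' fixed error log-odds for each condition cell plus participant-specific
#' random effects (a random intercept and a random slope on
#' intervening-task presence). Working-memory errors use one log-odds per
#' (modality x domain x intervening) cell; intervening-task errors use one
#' log-odds per (intervening condition x working-memory cell).
#'
#' Defaults emulate the qualitative error structure of the study: lower
#' working-memory error rates when sensory modality suits the information
#' domain (auditory-temporal, visual-spatial), interference from the
#' auditory intervening tasks concentrated on auditory-temporal
#' working-memory cells, and an easier spatial than temporal intervening
#' judgment with elevated errors when the working-memory load matches the
#' intervening task in modality.
#'
#' @param wm_logodds named numeric vector of error log-odds keyed
#'   `"modality.domain.intervening"` (e.g. `"auditory.temporal.AT"`). Keys
#'   missing from the vector fall back to `default_logodds`.
#' @param intervening_logodds named numeric vector keyed
#'   `"intervening.modality.domain"` for intervening-task errors.
#' @param default_logodds fallback log-odds for unspecified cells.
#' @param re_intercept_sd,re_slope_sd standard deviations of the participant
#'   random intercept and of the random slope on intervening-task presence
#'   (log-odds scale).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(wm_logodds = default_wm_logodds(),
                           intervening_logodds = default_intervening_logodds(),
                           default_logodds = 0,
                           re_intercept_sd = 0.5,
                           re_slope_sd = 0.3) {
  stopifnot(re_intercept_sd >= 0, re_slope_sd >= 0)
  structure(list(wm_logodds = wm_logodds,
                 intervening_logodds = intervening_logodds,
                 default_logodds = default_logodds,
                 re_intercept_sd = re_intercept_sd,
                 re_slope_sd = re_slope_sd),
            class = "observer_model")
}

#' @rdname observer_model
#' @export
guessing_observer <- function() {
  observer_model(wm_logodds = numeric(0), intervening_logodds = numeric(0),
                 default_logodds = 0, re_intercept_sd = 0, re_slope_sd = 0)
}

wm_cell_key <- function(modality, domain, intervening)
  paste(modality, domain, intervening, sep = ".")

int_cell_key <- function(intervening, modality, domain)
  paste(intervening, modality, domain, sep = ".")

#' @rdname observer_model
#' @export
default_wm_logodds <- function() {
  base <- c(auditory.temporal = stats::qlogis(0.15),
            auditory.spatial  = stats::qlogis(0.35),
            visual.temporal   = stats::qlogis(0.32),
            visual.spatial    = stats::qlogis(0.18))
  # interference (log-odds shift) from each intervening task on each WM cell
  shift <- c(auditory.temporal.none = 0, auditory.temporal.AT = 1.0,
             auditory.temporal.AS = 0.9,
             auditory.spatial.none = 0, auditory.spatial.AT = 0.05,
             auditory.spatial.AS = 0.05,
             visual.temporal.none = 0, visual.temporal.AT = 0.35,
             visual.temporal.AS = 0.3,
             visual.spatial.none = 0, visual.spatial.AT = 0.3,
             visual.spatial.AS = 0.35)
  out <- shift
  for (k in names(shift)) {
    cell <- sub("\\.(none|AT|AS)$", "", k)
    out[k] <- base[[cell]] + shift[[k]]
  }
  out
}

#' @rdname observer_model
#' @export
default_intervening_logodds <- function() {
  base <- c(AT = stats::qlogis(0.28), AS = stats::qlogis(0.12))
  out <- numeric(0)
  for (task in c("AT", "AS")) {
    for (m in c("auditory", "visual")) {
      for (d in c("temporal", "spatial")) {
        shift <- 0
        if (m == "auditory" && d == "temporal") shift <- 0.9   # matched auditory load
        if (task == "AS" && m == "auditory" && d == "spatial") shift <- 0.8
        if (task == "AT" && m == "auditory" && d == "spatial") shift <- 0.2
        out[int_cell_key(task, m, d)] <- base[[task]] + shift
      }
    }
  }
  out
}

lookup_logodds <- function(tab, keys, default) {
  out <- unname(tab[keys])
  out[is.na(out)] <- default
  out
}

#' Simulate behavioral responses for a design
#'
#' Draws per-trial working-memory and intervening-task errors from the
#' observer's logistic model: error log-odds = cell fixed effect +
#' participant random intercept + participant random slope (applied on
#' trials with an intervening task). Responses are derived from the errors:
#' a working-memory error reports the wrong same/different label, an
#' intervening error reports the wrong interval/side. A guessing observer
#' (all log-odds zero, no random effects) errs with probability 0.5.
#'
#' @param design a `trial_table`, typically from [generate_stimuli()].
#' @param observer an [observer_model()].
#' @param seed integer seed.
#' @return The design with columns `wm_response`, `wm_error`, `wm_correct`,
#'   and (on intervening trials with stimuli attached)
#'   `intervening_response`, `intervening_error`, `intervening_correct`.
#' @export
simulate_behavior <- function(design, observer = observer_model(),
                              seed = NULL) {
  stopifnot(inherits(observer, "observer_model"))
  cfg <- attr(design, "config")
  if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$seed else 1L

  parts <- sort(unique(design$participant))
  with_seed(derive_seed(seed, "behavior"), {
    b0 <- stats::rnorm(length(parts), 0, observer$re_intercept_sd)
    b1 <- stats::rnorm(length(parts), 0, observer$re_slope_sd)
    names(b0) <- names(b1) <- parts

    intv_present <- design$intervening != "none"
    pidx <- as.character(design$participant)

    wm_lo <- lookup_logodds(observer$wm_logodds,
                            wm_cell_key(design$wm_modality, design$wm_domain,
                                        design$intervening),
                            observer$default_logodds) +
      b0[pidx] + b1[pidx] * intv_present
    wm_error <- stats::runif(nrow(design)) < stats::plogis(wm_lo)

    design$wm_error <- wm_error
    design$wm_response <- ifelse(wm_error,
                                 ifelse(design$trial_type == "same", "different", "same"),
                                 design$trial_type)
    design$wm_correct <- !wm_error

    design$intervening_error <- NA
    design$intervening_response <- NA_character_
    design$intervening_correct <- NA
    if (any(intv_present)) {
      int_lo <- lookup_logodds(observer$intervening_logodds,
                               int_cell_key(design$intervening,
                                            design$wm_modality,
                                            design$wm_domain),
                               observer$default_logodds)[intv_present] +
        b0[pidx[intv_present]] + b1[pidx[intv_present]]
      ierr <- stats::runif(sum(intv_present)) < stats::plogis(int_lo)
      design$intervening_error[intv_present] <- ierr
      design$intervening_correct[intv_present] <- !ierr
      if (!is.null(design$intervening_seq)) {
        answers <- vapply(design$intervening_seq[intv_present], function(s)
          if (is.null(s)) NA_character_ else s$correct_answer, character(1))
        flip <- function(a) {
          out <- a
          out[a == "first"] <- "second"; out[a == "second"] <- "first"
          out[a == "left"] <- "right"; out[a == "right"] <- "left"
          out
        }
        design$intervening_response[intv_present] <-
          ifelse(ierr, flip(answers), answers)
      }
    }
  })
  design
}
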
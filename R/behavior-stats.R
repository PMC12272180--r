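#' Build a behavioral analysis table from a simulated design
#'
#' Reshapes a simulated `trial_table` into the one-row-per-trial table the
#' behavioral models consume. For the working-memory task all trials are
#' used; for the intervening task only trials with an intervening task.
#' `wm_condition` is the 4-level condition label (AT, AS, VT, VS).
#'
#' @param design a `trial_table` with responses (see [simulate_behavior()]).
#' @param task `"wm"` or `"intervening"`.
#' @return Data frame: `participant`, `wm_modality`, `wm_domain`,
#'   `wm_condition`, `intervening`, `error` (logical).
#' @export
behavioral_table <- function(design, task = c("wm", "intervening")) {
  task <- match.arg(task)
  cond_label <- paste0(toupper(substr(design$wm_modality, 1, 1)),
                       toupper(substr(design$wm_domain, 1, 1)))
  tab <- data.frame(participant = design$participant,
                    wm_modality = design$wm_modality,
                    wm_domain = design$wm_domain,
                    wm_condition = cond_label,
                    intervening = design$intervening,
                    stringsAsFactors = FALSE)
  if (task == "wm") {
    tab$error <- design$wm_error
  } else {
    keep <- design$intervening != "none"
    tab <- tab[keep, , drop = FALSE]
    tab$error <- design$intervening_error[keep]
  }
  rownames(tab) <- NULL
  tab
}

#' Specification of a behavioral mixed-effects model
#'
#' Two logistic mixed models are supported. The intervening-task model
#' regresses intervening-task errors on the 4-level working-memory
#' condition crossed with the intervening-task type, with per-participant
#' random intercepts and slopes for both predictors. The working-memory
#' model regresses recall errors on working-memory modality x domain x
#' intervening condition (3-level, including none), with per-participant
#' random intercepts and slopes for each predictor. Contrasts are treatment
#' coded with configurable baseline levels (defaults: auditory, temporal,
#' none).
#'
#' @param formula_id `"wm_model"` or `"intervening_model"`.
#' @param baselines named list of baseline levels per factor.
#' @param random random-effects structure: `"full"` (correlated slopes),
#'   `"uncorrelated"`, or `"intercept"`; this is the starting point of the
#'   fallback sequence.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(formula_id = c("wm_model", "intervening_model"),
                       baselines = NULL, random = "full") {
  formula_id <- match.arg(formula_id)
  defaults <- if (formula_id == "wm_model")
    list(wm_modality = "auditory", wm_domain = "temporal", intervening = "none")
  else list(wm_condition = "AT", intervening = "AT")
  if (!is.null(baselines)) defaults[names(baselines)] <- baselines
  structure(list(formula_id = formula_id, baselines = defaults,
                 random = random),
            class = "model_spec")
}

spec_factors <- function(spec) {
  if (spec$formula_id == "wm_model")
    c("wm_modality", "wm_domain", "intervening")
  else c("wm_condition", "intervening")
}

spec_formula <- function(spec, random) {
  fx <- paste(spec_factors(spec), collapse = " * ")
  re_terms <- paste(spec_factors(spec), collapse = " + ")
  re <- switch(random,
               full = sprintf("(1 + %s | participant)", re_terms),
               uncorrelated = sprintf("(1 + %s || participant)", re_terms),
               intercept = "(1 | participant)")
  stats::as.formula(paste0("error ~ ", fx, " + ", re))
}

apply_baselines <- function(table, spec) {
  for (f in names(spec$baselines)) {
    if (!spec$baselines[[f]] %in% table[[f]])
      stop("baseline level '", spec$baselines[[f]],
           "' not present in factor ", f)
    table[[f]] <- stats::relevel(factor(table[[f]]), ref = spec$baselines[[f]])
  }
  table$participant <- factor(table$participant)
  table
}

#' Fit a logistic mixed-effects behavioral model
#'
#' Fits the model described by the spec with `lme4::glmer` (binomial,
#' logit). If the requested random-effects structure fails to converge, the
#' structure is simplified stepwise (correlated slopes -> uncorrelated
#' slopes -> intercept only), each step reported via `message()`, never
#' silently.
#'
#' @param table a behavioral table (see [behavioral_table()]).
#' @param spec a [model_spec()].
#' @param nAGQ passed to `lme4::glmer`; `0` trades a little accuracy for a
#'   large speedup in simulation studies.
#' @return An object of class `glmm_fit`: `fit` (the merMod), `spec`,
#'   `random_structure` actually used, `coefficients` (fixed effects with
#'   SE, z, p).
#' @export
fit_glmm <- function(table, spec, nAGQ = 1) {
  pooled <- tapply(table$error, table[spec_factors(spec)], mean)
  if (any(pooled %in% c(0, 1), na.rm = TRUE))
    stop("complete separation: a condition cell has all-0 or all-1 errors (",
         paste(names(which(pooled %in% c(0, 1))), collapse = ", "), ")")
  table <- apply_baselines(table, spec)
  ladder <- c("full", "uncorrelated", "intercept")
  ladder <- ladder[match(spec$random, ladder):length(ladder)]
  if (nlevels(table$participant) < 2) ladder <- character(0)
  fit <- NULL
  used <- NULL
  for (structure_try in ladder) {
    res <- tryCatch({
      f <- lme4::glmer(spec_formula(spec, structure_try), data = table,
                       family = stats::binomial(), nAGQ = nAGQ)
      conv <- f@optinfo$conv$lme4
      if (!is.null(conv$code) && conv$code != 0) stop("nonconvergence")
      f
    }, warning = function(w) w, error = function(e) e)
    if (inherits(res, "merMod")) {
      fit <- res
      used <- structure_try
      break
    }
    message("random structure '", structure_try, "' failed (",
            conditionMessage(res), "); simplifying")
  }
  if (is.null(fit)) {
    # random-effects variance unestimable (e.g. one participant): the model
    # collapses to ordinary logistic regression on the fixed effects
    message("random effects unestimable; fitting fixed effects only")
    fx <- paste(spec_factors(spec), collapse = " * ")
    fit <- stats::glm(stats::as.formula(paste0("error ~ ", fx)),
                      family = stats::binomial(), data = table)
    used <- "none"
  }
  if (length(ladder) && used != ladder[1])
    message("fitted with simplified random structure: ", used)
  cf <- summary(fit)$coefficients
  out <- structure(list(fit = fit, spec = spec, random_structure = used,
                        coefficients = data.frame(
                          term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                          z = cf[, 3], p = cf[, 4], row.names = NULL)),
                   class = "glmm_fit")
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Logistic mixed model (%s), random structure: %s\n",
              x$spec$formula_id, x$random_structure))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Omnibus tests on the model coefficients
#'
#' Type-III Wald chi-square tests per main effect and interaction of a
#' fitted behavioral model (via `car::Anova`). For linear mixed models the
#' same call reports F tests; for the binomial models fitted here the
#' chi-square form matches the omnibus statistics reported for this class
#' of analysis.
#'
#' @param fit a `glmm_fit`.
#' @return Data frame: `term`, `chisq`, `df`, `p`.
#' @export
anova_on_coefficients <- function(fit) {
  a <- car::Anova(fit$fit, type = 3)
  keep <- rownames(a) != "(Intercept)"
  data.frame(term = rownames(a)[keep],
             chisq = a$Chisq[keep],
             df = a$Df[keep],
             p = a[["Pr(>Chisq)"]][keep],
             row.names = NULL)
}

#' Post-hoc pairs for the two behavioral models
#'
#' The comparisons of interest: for the working-memory model, contrasts
#' between intervening conditions within each working-memory condition
#' cell; for the intervening model, contrasts between working-memory
#' conditions within each intervening task.
#'
#' @return Data frame with columns `factor`, `level_a`, `level_b`, and the
#'   restriction columns fixing the remaining factors' levels.
#' @export
wm_posthoc_pairs <- function() {
  cells <- expand.grid(wm_modality = c("auditory", "visual"),
                       wm_domain = c("temporal", "spatial"),
                       stringsAsFactors = FALSE)
  pairs <- data.frame(level_a = c("AT", "AS", "AS"),
                      level_b = c("none", "none", "AT"))
  out <- merge(cells, pairs)
  out$factor <- "intervening"
  out[, c("factor", "level_a", "level_b", "wm_modality", "wm_domain")]
}

#' @rdname wm_posthoc_pairs
#' @export
intervening_posthoc_pairs <- function() {
  conds <- c("AT", "AS", "VT", "VS")
  pairs <- t(utils::combn(conds, 2))
  out <- data.frame(factor = "wm_condition",
                    level_a = pairs[, 2], level_b = pairs[, 1])
  out <- merge(out, data.frame(intervening = c("AT", "AS")))
  out[, c("factor", "level_a", "level_b", "intervening")]
}

#' Pairwise simple effects by baseline cycling
#'
#' Re-fits the treatment-coded model under rotated baseline assignments
#' until a coefficient (and Wald p-value) exists for every requested pair:
#' the restriction columns of `needed_pairs` set the baselines of the other
#' factors, `level_b` becomes the baseline of the target factor, and the
#' simple effect of `level_a` vs `level_b` within that cell is read from
#' the corresponding first-order coefficient. Fits are cached per baseline
#' assignment.
#'
#' @param table a behavioral table.
#' @param spec a [model_spec()].
#' @param needed_pairs data frame as from [wm_posthoc_pairs()] /
#'   [intervening_posthoc_pairs()].
#' @param alpha familywise error level for the Holm-Bonferroni correction.
#' @param nAGQ passed to [fit_glmm()].
#' @return Data frame of class `posthoc_result`: one row per pair with
#'   `beta` (log-odds, level_a minus level_b), `se`, `p_raw`, `p_holm`,
#'   `significant`.
#' @export
cycle_baselines <- function(table, spec, needed_pairs, alpha = 0.05,
                            nAGQ = 1) {
  factors <- spec_factors(spec)
  restrict_cols <- setdiff(names(needed_pairs),
                           c("factor", "level_a", "level_b"))
  bad <- needed_pairs$factor[!needed_pairs$factor %in% factors]
  if (length(bad)) stop("pairs reference unknown factors: ",
                        paste(unique(bad), collapse = ", "))
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(needed_pairs))
  for (i in seq_len(nrow(needed_pairs))) {
    pr <- needed_pairs[i, , drop = FALSE]
    base <- spec$baselines
    base[[pr$factor]] <- pr$level_b
    for (rc in restrict_cols) if (rc %in% factors) base[[rc]] <- pr[[rc]]
    key <- paste(unlist(base[factors]), collapse = "|")
    if (!exists(key, envir = cache)) {
      assign(key, fit_glmm(table,
                           model_spec(spec$formula_id, baselines = base,
                                      random = spec$random),
                           nAGQ = nAGQ),
             envir = cache)
    }
    fit <- cache[[key]]
    term <- paste0(pr$factor, pr$level_a)
    cf <- fit$coefficients
    hit <- cf[cf$term == term, , drop = FALSE]
    if (nrow(hit) != 1)
      stop("pair not reachable under the model formula: ",
           pr$factor, " ", pr$level_a, " vs ", pr$level_b)
    rows[[i]] <- cbind(pr, data.frame(beta = hit$beta, se = hit$se,
                                      p_raw = hit$p))
  }
  out <- do.call(rbind, rows)
  hb <- holm_bonferroni(out$p_raw, alpha = alpha)
  out$p_holm <- hb$p_adjusted
  out$significant <- hb$significant
  rownames(out) <- NULL
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and declares the i-th smallest significant
#' only if every j-th smallest with j <= i satisfies
#' `p_(j) <= alpha / (m - j + 1)` (step-down rule). Implemented through the
#' standard Holm adjustment; making any p-value smaller can never turn a
#' significant result non-significant.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha familywise error level.
#' @return List: `significant` (logical, original order), `p_adjusted`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values))) stop("p-values must be finite")
  adj <- stats::p.adjust(p_values, method = "holm")
  list(significant = adj <= alpha, p_adjusted = adj)
}
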
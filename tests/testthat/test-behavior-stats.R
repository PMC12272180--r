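test_that("behavioral tables have the documented shape", {
  d <- generate_design(experiment_config(n_participants = 2, seed = 81))
  db <- simulate_behavior(d, guessing_observer(), seed = 81)
  wm <- behavioral_table(db, "wm")
  expect_equal(nrow(wm), nrow(d))
  expect_true(all(wm$wm_condition %in% c("AT", "AS", "VT", "VS")))
  iv <- behavioral_table(db, "intervening")
  expect_equal(nrow(iv), sum(d$intervening != "none"))
  expect_false(any(iv$intervening == "none"))
  expect_false(anyNA(iv$error))
})

test_that("a single-participant fit reduces to ordinary logistic regression", {
  d <- generate_design(experiment_config(n_participants = 1, seed = 82))
  db <- simulate_behavior(d, observer_model(re_intercept_sd = 0,
                                            re_slope_sd = 0), seed = 82)
  tab <- behavioral_table(db, "wm")
  fit <- suppressMessages(fit_glmm(tab, model_spec("wm_model",
                                                   random = "intercept")))
  glm_fit <- stats::glm(error ~ wm_modality * wm_domain * intervening,
                        family = stats::binomial(),
                        data = dualtaskr:::apply_baselines(
                          tab, model_spec("wm_model")))
  expect_equal(fit$coefficients$beta, unname(stats::coef(glm_fit)),
               tolerance = 1e-3)
})

test_that("a null generator yields near-zero coefficients", {
  d <- generate_design(experiment_config(n_participants = 10, seed = 83))
  db <- simulate_behavior(d, guessing_observer(), seed = 83)
  tab <- behavioral_table(db, "wm")
  fit <- suppressMessages(fit_glmm(tab, model_spec("wm_model",
                                                   random = "intercept"),
                                   nAGQ = 0))
  ci_lo <- fit$coefficients$beta - 2.6 * fit$coefficients$se
  ci_hi <- fit$coefficients$beta + 2.6 * fit$coefficients$se
  expect_gt(mean(ci_lo <= 0 & 0 <= ci_hi), 0.85)
})

test_that("separation and missing baseline levels raise clear errors", {
  d <- generate_design(experiment_config(n_participants = 1, seed = 84))
  db <- simulate_behavior(d, guessing_observer(), seed = 84)
  tab <- behavioral_table(db, "wm")
  tab$error[tab$wm_modality == "auditory" & tab$wm_domain == "temporal" &
              tab$intervening == "none"] <- FALSE
  expect_error(fit_glmm(tab, model_spec("wm_model")), "separation")
  tab2 <- behavioral_table(db, "wm")
  expect_error(fit_glmm(tab2, model_spec("wm_model",
                                         baselines = list(intervening = "XX"))),
               "not present")
})

test_that("omnibus tests are deterministic and near-null under a null generator", {
  d <- generate_design(experiment_config(n_participants = 8, seed = 85))
  db <- simulate_behavior(d, guessing_observer(), seed = 85)
  tab <- behavioral_table(db, "intervening")
  fit <- suppressMessages(fit_glmm(tab, model_spec("intervening_model",
                                                   random = "intercept"),
                                   nAGQ = 0))
  a1 <- anova_on_coefficients(fit)
  a2 <- anova_on_coefficients(fit)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 3)   # two mains + interaction
  expect_true(all(a1$p > 1e-4))
})

test_that("baseline cycling reproduces two-level sign flips and all pairs", {
  d <- generate_design(experiment_config(n_participants = 6, seed = 86))
  db <- simulate_behavior(d, observer_model(), seed = 86)
  tab <- behavioral_table(db, "intervening")
  spec <- model_spec("intervening_model", random = "intercept")
  pairs <- intervening_posthoc_pairs()
  ph <- suppressMessages(cycle_baselines(tab, spec, pairs, nAGQ = 0))
  expect_equal(nrow(ph), 12)   # 6 wm-condition pairs x 2 intervening tasks
  expect_equal(anyDuplicated(ph[, c("level_a", "level_b", "intervening")]), 0)
  # two-sided symmetry: swapping the pair flips beta, keeps p
  swapped <- data.frame(factor = "wm_condition",
                        level_a = pairs$level_b[1],
                        level_b = pairs$level_a[1],
                        intervening = pairs$intervening[1])
  ph2 <- suppressMessages(cycle_baselines(tab, spec, swapped, nAGQ = 0))
  expect_equal(ph2$beta, -ph$beta[1], tolerance = 1e-4)
  expect_equal(ph2$p_raw, ph$p_raw[1], tolerance = 1e-3)
})

test_that("unreachable pairs are reported by name", {
  d <- generate_design(experiment_config(n_participants = 4, seed = 87))
  db <- simulate_behavior(d, guessing_observer(), seed = 87)
  tab <- behavioral_table(db, "wm")
  bad <- data.frame(factor = "wm_flavour", level_a = "x", level_b = "y")
  expect_error(cycle_baselines(tab, model_spec("wm_model"), bad),
               "unknown factors")
})

test_that("Holm-Bonferroni matches hand-stepped computations exactly", {
  # single p at the plain alpha level
  expect_true(holm_bonferroni(0.04)$significant)
  # thresholds 0.05/3, 0.05/2, 0.05: all pass stepwise
  h <- holm_bonferroni(c(0.01, 0.02, 0.04))
  expect_equal(h$significant, c(TRUE, TRUE, TRUE))
  # first threshold 0.0167 fails, so none survive
  h2 <- holm_bonferroni(c(0.03, 0.03, 0.03))
  expect_equal(h2$significant, c(FALSE, FALSE, FALSE))
  # order-independence
  h3 <- holm_bonferroni(c(0.04, 0.01, 0.02))
  expect_equal(h3$significant, c(TRUE, TRUE, TRUE))
})

test_that("Holm is monotone in the p-values", {
  set.seed(88)
  for (r in 1:50) {
    p <- stats::runif(6)
    sig <- holm_bonferroni(p)$significant
    p2 <- p
    j <- sample.int(6, 1)
    p2[j] <- p2[j] * stats::runif(1)
    sig2 <- holm_bonferroni(p2)$significant
    expect_true(all(sig2 >= sig))
  }
})

test_that("fitted cell probabilities track empirical error rates", {
  d <- generate_design(experiment_config(n_participants = 12, seed = 89))
  db <- simulate_behavior(d, observer_model(re_intercept_sd = 0.2,
                                            re_slope_sd = 0), seed = 89)
  tab <- behavioral_table(db, "wm")
  fit <- suppressMessages(fit_glmm(tab, model_spec("wm_model",
                                                   random = "intercept"),
                                   nAGQ = 0))
  cells <- unique(tab[, c("wm_modality", "wm_domain", "intervening")])
  newd <- dualtaskr:::apply_baselines(
    cbind(cells, participant = tab$participant[1]), model_spec("wm_model"))
  pred <- stats::predict(fit$fit, newdata = newd, re.form = NA,
                         type = "response")
  emp <- mapply(function(m, dm, iv)
    mean(tab$error[tab$wm_modality == m & tab$wm_domain == dm &
                     tab$intervening == iv]),
    cells$wm_modality, cells$wm_domain, cells$intervening)
  expect_lt(max(abs(pred - emp)), 0.08)
})
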
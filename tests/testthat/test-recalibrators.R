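test_that("training fit recovers generating coefficients at the study's sample size", {
  cfg <- united_config(seed = 41)
  cc <- generate_case_control(cfg)
  fit <- quiet(fit_training_model(cc, mcmc = mcmc_fast(seed = 41)))
  expect_equal(fit$training_odds, 177 / 278)
  s <- summary(fit$posterior)
  truth <- cfg$true_coefficients
  for (v in names(truth)) {
    row <- s[s$parameter == v, ]
    expect_true(truth[[v]] >= row$q2.5 && truth[[v]] <= row$q97.5,
                info = v)
  }
})

test_that("training fit rejects degenerate inputs", {
  cfg <- united_config(seed = 42)
  cc <- generate_case_control(cfg)
  all_cases <- cc[cc$disease_label == 1, ]
  expect_error(fit_training_model(all_cases),
               "case-control|cases and controls")
  pop <- generate_population(cfg)
  expect_error(fit_training_model(pop), "case-control")
})

test_that("null generating coefficients yield null posterior slopes", {
  cfg <- generator_config(
    n_cases = 300, n_controls = 300, prevalence_target = 0.2,
    true_coefficients = c(parent_affected = 0, age_at_recruitment = 0,
                          hba1c = 0, age_at_diagnosis = 0, sex = 0),
    seed = 43)
  cc <- generate_case_control(cfg)
  fit <- quiet(fit_training_model(cc, mcmc = mcmc_fast(seed = 43)))
  s <- summary(fit$posterior)
  slopes <- s[s$parameter != "intercept", ]
  expect_true(all(abs(slopes$mean) < 3 * slopes$sd))
})

test_that("training predictions reduce to the intercept for a zero covariate vector", {
  fit <- pinned_training_fit(
    c(intercept = -1.3, parent_affected = 3.22, age_at_recruitment = -0.09,
      hba1c = -0.68, age_at_diagnosis = 0.10, sex = 1.35),
    training_odds = 177 / 278)
  zero <- data.frame(sex = 0, parent_affected = 0, age_at_diagnosis = 0,
                     age_at_recruitment = 0, bmi = 25, hba1c = 0)
  p <- predict_training(fit, zero)
  expect_equal(unique(as.vector(p)), inv_logit(-1.3))
  subj <- data.frame(sex = 1, parent_affected = 1, age_at_diagnosis = 20,
                     age_at_recruitment = 30, bmi = 25, hba1c = 8)
  expect_true(all(predict_training(fit, subj) > 0 &
                    predict_training(fit, subj) < 1))
  subj_bad <- subj
  subj_bad$hba1c <- NA
  expect_error(predict_training(fit, subj_bad), "hba1c")
})

test_that("conversion-table arithmetic matches hand-computed odds updating", {
  # construct training scores whose sensitivity/specificity at threshold
  # 0.5 are exactly 0.8 and 0.9
  probs <- c(rep(0.6, 8), rep(0.4, 2),   # cases: 8 of 10 above 0.5
             rep(0.3, 9), rep(0.7, 1))   # controls: 9 of 10 below 0.5
  labels <- c(rep(1, 10), rep(0, 10))
  tab <- build_conversion_table(probs, labels,
                                band_edges = c(0, 0.5, 1),
                                target_prevalence = 0.006)
  # LR+ = 0.8 / 0.1 = 8; post odds = 8 * 0.006/0.994; post prob = odds/(1+odds)
  post_odds <- 8 * 0.006 / 0.994
  expect_equal(tab$bands$output[2], post_odds / (1 + post_odds),
               tolerance = 1e-12)
  expect_equal(tab$bands$output[2], 0.046066, tolerance = 1e-4)
  expect_equal(tab$bands$output[1], 0.006)
  # floor property: no band below the target prevalence
  expect_true(all(tab$bands$output >= 0.006))
})

test_that("recalibrating to the training prevalence reproduces the empirical post-test rates", {
  # when the target prevalence equals the sample prevalence, the likelihood
  # ratio update is Bayes' theorem on the same sample, so each band output
  # must equal the empirical P(case | score > threshold) exactly
  set.seed(55)
  n <- 50000
  p <- stats::rbeta(n, 2, 3)
  y <- stats::rbinom(n, 1, p)
  tab <- build_conversion_table(p, y, target_prevalence = mean(y))
  for (i in 2:10) {
    thr <- tab$bands$lower[i]
    expect_equal(tab$bands$output[i], mean(y[p > thr]), tolerance = 1e-12)
  }
  # post-test rates rise with the threshold for informative scores
  expect_true(all(diff(tab$bands$output) > -1e-12))
})

test_that("band lookup honors the bracket conventions", {
  tab <- build_conversion_table(c(0.2, 0.8), c(0, 1),
                                target_prevalence = 0.05)
  out <- tab$bands$output
  expect_equal(apply_conversion(tab, 1.0), out[10])    # closed last band
  expect_equal(apply_conversion(tab, 0.10), out[2])    # [10, 20) includes 0.10
  expect_equal(apply_conversion(tab, 0.0999), out[1])
  expect_equal(apply_conversion(tab, 0.13), apply_conversion(tab, 0.17))
  expect_error(apply_conversion(tab, 0), "\\(0, 1\\]")
  expect_error(apply_conversion(tab, 1.2), "\\(0, 1\\]")
  # piecewise-constant output: at most one value per band
  expect_lte(length(unique(apply_conversion(tab, seq(0.01, 1, 0.01)))), 10)
})

test_that("offset predictions shift log-odds by a constant and preserve ranking", {
  fit <- pinned_training_fit(
    c(intercept = 1.85, parent_affected = 3.22, age_at_recruitment = -0.09,
      hba1c = -0.68, age_at_diagnosis = 0.10, sex = 1.35),
    training_odds = 177 / 278)
  set.seed(66)
  newdata <- raremix:::sample_covariates(
    200, united_config()$covariate_distributions)
  base <- predict_training(fit, newdata)
  same <- albert_offset_predict(fit, newdata, odds_target = 177 / 278)
  expect_equal(same, base, tolerance = 1e-12)
  shifted <- albert_offset_predict(fit, newdata,
                                   odds_target = 0.006 / 0.994)
  expect_equal(order(colMeans(shifted)), order(colMeans(base)))
  expect_equal(auroc(colMeans(shifted), rep(0:1, 100)),
               auroc(colMeans(base), rep(0:1, 100)))
  expect_error(albert_offset_predict(fit, newdata, odds_target = -1),
               "positive")
})

test_that("offset recalibration with true coefficients is calibrated in the large", {
  cfg <- united_config(seed = 71, n_population = 50000)
  pop <- generate_population(cfg)
  # the case-control-scale model implied by outcome sampling at case
  # fraction f differs from the population model only in its intercept
  truth <- generating_coefficients(pop, cfg)
  f_odds <- (177 / 455) / (278 / 455)
  pop_odds <- 0.006 / 0.994
  cc_coefs <- truth
  cc_coefs["intercept"] <- truth["intercept"] + log(f_odds) - log(pop_odds)
  fit <- pinned_training_fit(cc_coefs, training_odds = f_odds)
  pr <- albert_offset_predict(fit, pop, odds_target = pop_odds)
  se <- sqrt(0.006 * 0.994 / 50000)
  expect_lt(abs(mean(colMeans(pr)) - 0.006), 3 * se)
})

test_that("re-estimation applies the scenario rules", {
  cfg <- united_config(seed = 81)
  pop <- apply_testing_cascade(generate_population(cfg))
  n_tested <- sum(pop$t_indicator == 0)
  fit_b <- quiet(fit_reestimation(pop, mcmc = mcmc_fast(seed = 81),
                                  scenario = "b"))
  expect_equal(fit_b$n_used, n_tested)
  expect_message(
    fa <- suppressWarnings(fit_reestimation(pop, mcmc = mcmc_fast(seed = 81),
                                            scenario = "a")),
    "imputing")
  expect_equal(fa$n_used, nrow(pop))
  expect_gt(fa$n_used, fit_b$n_used)
  # zero cases after filtering fails
  no_cases <- pop
  no_cases$disease_label[no_cases$disease_label == 1] <- 0L
  expect_error(quiet(fit_reestimation(no_cases, scenario = "b")), "cases")
})

test_that("re-estimation is consistent at large n", {
  cfg <- generator_config(n_population = 100000, prevalence_target = 0.05,
                          seed = 82)
  pop <- generate_population(cfg)
  fit <- quiet(fit_reestimation(pop,
                                mcmc = mcmc_config(n_chains = 2,
                                                   n_iterations = 4000,
                                                   n_burnin = 1500,
                                                   seed = 82),
                                scenario = "a"))
  s <- summary(fit$posterior)
  truth <- cfg$true_coefficients
  for (v in names(truth)) {
    row <- s[s$parameter == v, ]
    expect_lt(abs(row$mean - truth[[v]]), 4 * row$sd + 0.02)
  }
})

test_that("joint recalibration recovers no-shift gamma and scaled-slope shifts", {
  # no shift: population drawn from the very model the training data follow
  cfg <- matched_config(n_population = 20000, seed = 91)
  cc <- generate_case_control(cfg)
  pop <- generate_population(cfg)
  fit <- quiet(fit_joint_recalibration(cc, pop, mcmc = mcmc_recal(seed = 91),
                                       scenario = "a"))
  g <- gamma_draws(fit)
  expect_lt(abs(mean(g[, "gamma0"])), 0.3)
  expect_lt(abs(mean(g[, "gamma1"]) - 1), 0.15)

  # all slopes halved in the population: gamma1 should track 0.5
  for (seed in c(92, 93, 94)) {
    cfg_t <- matched_config(n_population = 20000, seed = seed)
    half <- cfg_t
    half$true_coefficients <- cfg_t$true_coefficients * 0.5
    cc_t <- generate_case_control(cfg_t)
    pop_h <- generate_population(half)
    fit_h <- quiet(fit_joint_recalibration(cc_t, pop_h,
                                           mcmc = mcmc_recal(seed = seed),
                                           scenario = "a"))
    g_h <- gamma_draws(fit_h)
    qs <- stats::quantile(g_h[, "gamma1"], c(0.025, 0.975))
    expect_true(qs[1] < 0.5 && qs[2] > 0.5,
                info = sprintf("seed %d: CI (%.2f, %.2f)", seed,
                               qs[1], qs[2]))
    expect_lt(abs(mean(g_h[, "gamma1"]) - 0.5), 0.2)
  }
})

test_that("the joint fit propagates more gamma uncertainty than the plug-in variant", {
  cfg <- matched_config(n_population = 3000, seed = 95)
  cc <- generate_case_control(cfg)
  pop <- generate_population(cfg)
  joint <- quiet(fit_joint_recalibration(cc, pop, mcmc = mcmc_fast(seed = 95),
                                         scenario = "a"))
  plugin <- quiet(fit_joint_recalibration(cc, pop,
                                          mcmc = mcmc_fast(seed = 95),
                                          scenario = "a",
                                          method = "plugin"))
  sd_joint <- apply(gamma_draws(joint), 2, stats::sd)
  sd_plugin <- apply(gamma_draws(plugin), 2, stats::sd)
  expect_gt(sd_joint[["gamma1"]], sd_plugin[["gamma1"]])
})

test_that("screening arithmetic helpers are exact", {
  expect_equal(pretest_probability(7, 1171) * 100, 0.5978, tolerance = 1e-3)
  expect_equal(positive_predictive_value(7, 39) * 100, 17.9487,
               tolerance = 1e-3)
  expect_equal(odds_to_prob(prob_to_odds(0.3)), 0.3)
  expect_error(pretest_probability(10, 5), "counts")
})
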
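test_that("generated population matches the target prevalence within binomial error", {
  cfg <- united_config(seed = 101, n_population = 200000)
  pop <- generate_population(cfg)
  prev <- mean(pop$disease_label)
  se <- sqrt(0.006 * 0.994 / 200000)
  expect_lt(abs(prev - 0.006), 3 * se)
})

test_that("generation is deterministic given the seed", {
  cfg <- united_config(seed = 5)
  expect_identical(generate_population(cfg), generate_population(cfg))
  expect_identical(generate_case_control(cfg), generate_case_control(cfg))
  cfg2 <- united_config(seed = 6)
  expect_false(identical(generate_population(cfg), generate_population(cfg2)))
})

test_that("default configuration reproduces the target cohort's biomarker composition", {
  cfg <- united_config(seed = 202, n_population = 100000)
  pop <- generate_population(cfg)
  p_cneg <- mean(pop$cpep_status == "negative")
  p_cpos_apos <- mean(pop$cpep_status == "positive" &
                        pop$antibody_status == "positive")
  p_tested <- mean(pop$t_indicator == 0)
  # realized composition of the emulated cohort: 924 / 151 / 96 of 1171
  expect_lt(abs(p_cneg - 924 / 1171), 0.02)
  expect_lt(abs(p_cpos_apos - 151 / 1171), 0.02)
  expect_lt(abs(p_tested - 96 / 1171), 0.02)
})

test_that("case-control sample has the requested composition and no biomarkers", {
  cfg <- united_config(seed = 7)
  cc <- generate_case_control(cfg)
  expect_equal(nrow(cc), 455)
  expect_equal(sum(cc$disease_label == 1), 177)
  expect_equal(sum(cc$disease_label == 1) / nrow(cc), 177 / 455)
  expect_true(all(is.na(cc$cpep_status)))
  expect_true(all(is.na(cc$antibody_status)))
  expect_error(generate_case_control(united_config(n_cases = 0)),
               "positive")
})

test_that("maximum likelihood on a large case-control sample recovers the generating slopes", {
  # outcome-dependent sampling leaves all non-intercept coefficients intact;
  # oracle is a plain ML logistic fit
  cfg <- generator_config(n_cases = 20000, n_controls = 30000,
                          prevalence_target = 0.3, seed = 11)
  cc <- generate_case_control(cfg)
  g <- stats::glm(disease_label ~ parent_affected + age_at_recruitment +
                    hba1c + age_at_diagnosis + sex,
                  family = stats::binomial(), data = cc)
  est <- stats::coef(g)[-1]
  se <- sqrt(diag(stats::vcov(g)))[-1]
  truth <- cfg$true_coefficients
  expect_true(all(abs(est - truth) < 4 * se))
})

test_that("case-control sampling preserves the covariate-specific likelihood ratio", {
  # fitting both designs at large n must give the same slopes (only the
  # intercept differs, by the sampling-odds offset)
  cfg <- generator_config(n_cases = 15000, n_controls = 20000,
                          n_population = 60000, prevalence_target = 0.3,
                          seed = 21)
  cc <- generate_case_control(cfg)
  pop <- generate_population(cfg)
  f <- disease_label ~ parent_affected + age_at_recruitment + hba1c +
    age_at_diagnosis + sex
  g_cc <- stats::glm(f, stats::binomial(), data = cc)
  g_pop <- stats::glm(f, stats::binomial(), data = pop)
  se <- sqrt(diag(stats::vcov(g_cc)) + diag(stats::vcov(g_pop)))[-1]
  expect_true(all(abs(stats::coef(g_cc)[-1] - stats::coef(g_pop)[-1]) <
                    4 * se))
})

test_that("the testing cascade masks exactly the screened-out labels", {
  cfg <- united_config(seed = 31)
  pop <- generate_population(cfg)
  masked <- apply_testing_cascade(pop)
  expect_equal(nrow(masked), nrow(pop))
  expect_equal(sum(!is.na(masked$disease_label)), sum(pop$t_indicator == 0))
  # covariates and biomarkers untouched
  expect_identical(masked[raremix:::COVARIATE_ORDER],
                   pop[raremix:::COVARIATE_ORDER])
  expect_identical(masked$t_indicator, pop$t_indicator)

  # all-tested cohort is returned unchanged
  all_tested <- pop
  all_tested$t_indicator <- 0L
  all_tested$cpep_status <- "positive"
  all_tested$antibody_status <- "negative"
  expect_identical(apply_testing_cascade(all_tested)$disease_label,
                   pop$disease_label)

  # fully screened-out cohort loses every label
  none_tested <- pop
  none_tested$t_indicator <- 1L
  none_tested$cpep_status <- "negative"
  expect_true(all(is.na(apply_testing_cascade(none_tested)$disease_label)))

  cc <- generate_case_control(cfg)
  expect_error(apply_testing_cascade(cc), "population")
})

test_that("covariate shift variants are validated and only move the population config", {
  cfg <- united_config()
  expect_error(covariate_shift_variant(cfg, list()), "empty")
  expect_error(covariate_shift_variant(cfg, list(covariate = "shoe_size",
                                                 coefficient_scale = 0.5)),
               "covariate")
  pair <- covariate_shift_variant(cfg, list(covariate = "hba1c",
                                            coefficient_scale = 1))
  expect_identical(pair$training, pair$population)
  pair <- covariate_shift_variant(cfg, list(covariate = "hba1c",
                                            coefficient_scale = 0.5))
  expect_identical(pair$training, cfg)
  expect_equal(pair$population$true_coefficients[["hba1c"]],
               cfg$true_coefficients[["hba1c"]] * 0.5)
})

test_that("dataset invariants are enforced", {
  cfg <- united_config(seed = 8)
  pop <- generate_population(cfg)
  bad <- as.data.frame(pop)
  bad$age_at_recruitment[3] <- bad$age_at_diagnosis[3] - 1
  expect_error(new_dataset(bad, "population"), "rows: 3")
  bad2 <- as.data.frame(pop)
  bad2$t_indicator[5] <- 1 - bad2$t_indicator[5]
  expect_error(new_dataset(bad2, "population"), "inconsistent")
  # unlabeled subjects must carry a known screening indicator
  bad3 <- as.data.frame(pop)
  bad3$disease_label[2] <- NA
  bad3$t_indicator[2] <- NA
  bad3$cpep_status[2] <- NA
  bad3$antibody_status[2] <- NA
  expect_error(new_dataset(bad3, "population"), "t_indicator")
  expect_error(generator_config(prevalence_target = 0.6), "rare")
})
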
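test_that("the constrained branch posterior is conjugate given observed membership", {
  # with T observed for everyone the branch probability is posterior-
  # independent of the other blocks, so its margin must match the
  # closed-form Beta update
  cfg <- united_config(seed = 51)
  cc <- generate_case_control(cfg)
  pop <- apply_testing_cascade(generate_population(cfg))
  fit <- quiet(fit_mixture(pop, mode = "recalibration", cc = cc,
                           mcmc = mcmc_config(n_chains = 2,
                                              n_iterations = 30000,
                                              n_burnin = 5000, thin = 5,
                                              seed = 51)))
  n1 <- fit$branch1_counts[["n"]]
  m1 <- fit$branch1_counts[["m"]]
  expect_equal(m1, 0)
  draws <- as.matrix(fit$posterior)[, "p_branch1"]
  a <- 2.2 + m1
  b <- 7361.3 + n1 - m1
  expect_lt(abs(mean(draws) - a / (a + b)) / (a / (a + b)), 0.02)
  # distributional agreement with the closed form
  ks <- suppressWarnings(stats::ks.test(draws, stats::pbeta,
                                        shape1 = a, shape2 = b))
  expect_lt(unname(ks$statistic), 0.02)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(mean(draws), 0.05)
})

test_that("recalibration-mixture gamma agrees with the plain joint recalibrator", {
  # the branch-0 block of the mixture is exactly the scenario-b joint
  # recalibration, and the other blocks are posterior-independent of it
  cfg <- united_config(seed = 52)
  cc <- generate_case_control(cfg)
  pop <- apply_testing_cascade(generate_population(cfg))
  mix <- quiet(fit_mixture(pop, mode = "recalibration", cc = cc,
                           mcmc = mcmc_recal(seed = 52)))
  plain <- quiet(fit_joint_recalibration(cc, pop, mcmc = mcmc_recal(seed = 52),
                                         scenario = "b"))
  g_mix <- colMeans(gamma_draws(mix))
  g_plain <- colMeans(gamma_draws(plain))
  sds <- apply(gamma_draws(plain), 2, stats::sd)
  expect_lt(abs(g_mix[["gamma0"]] - g_plain[["gamma0"]]),
            0.5 * sds[["gamma0"]])
  expect_lt(abs(g_mix[["gamma1"]] - g_plain[["gamma1"]]),
            0.5 * sds[["gamma1"]])
})

test_that("mixture fit validates its inputs", {
  cfg <- united_config(seed = 53)
  cc <- generate_case_control(cfg)
  pop <- apply_testing_cascade(generate_population(cfg))
  expect_error(fit_mixture(pop, mode = "recalibration"), "case-control")
  bad <- pop
  bad$t_indicator[1] <- NA
  bad$disease_label[1] <- 0L
  expect_error(fit_mixture(bad, mode = "reestimation"), "t_indicator")
  expect_error(fit_mixture(cc, mode = "reestimation"), "population")
})

test_that("mixture predictions interpolate between their branches", {
  cfg <- united_config(seed = 54)
  cc <- generate_case_control(cfg)
  pop <- apply_testing_cascade(generate_population(cfg))
  fit <- quiet(fit_mixture(pop, mode = "recalibration", cc = cc,
                           mcmc = mcmc_fast(seed = 54)))
  subjects <- as.data.frame(pop[1:10, ])
  p1 <- predict_mixture(fit, subjects, "T1")
  p0 <- predict_mixture(fit, subjects, "T0")
  punk <- predict_mixture(fit, subjects, "unknown")
  # forced endpoints
  expect_equal(predict_mixture(fit, subjects, "unknown", q_override = 0),
               p0, tolerance = 1e-12)
  expect_equal(predict_mixture(fit, subjects, "unknown", q_override = 1),
               p1, tolerance = 1e-12)
  # convexity, draw-wise
  expect_true(all(punk >= pmin(p1, p0) - 1e-12 &
                    punk <= pmax(p1, p0) + 1e-12))
  # fixed-weight arithmetic
  half <- 0.5 * p1 + 0.5 * p0
  expect_equal(predict_mixture(fit, subjects, "unknown", q_override = 0.5),
               half, tolerance = 1e-12)
  # screened-out subjects are constrained near zero
  expect_lt(max(colMeans(p1)), 0.01)
})

test_that("an all-tested cohort reduces the mixture to the plain recalibrator", {
  cfg <- generator_config(
    seed = 56, n_population = 1500, prevalence_target = 0.05,
    biomarker_conditional_probs = c(cpep_pos_disease = 1,
                                    cpep_pos_healthy = 1,
                                    ab_pos_disease = 0,
                                    ab_pos_healthy = 0))
  cc <- generate_case_control(cfg)
  pop <- generate_population(cfg)
  expect_true(all(pop$t_indicator == 0))
  mix <- quiet(fit_mixture(pop, mode = "recalibration", cc = cc,
                           mcmc = mcmc_fast(seed = 56)))
  plain <- quiet(fit_joint_recalibration(cc, pop, mcmc = mcmc_fast(seed = 56),
                                         scenario = "b"))
  subjects <- as.data.frame(pop[1:50, ])
  pm <- colMeans(predict_mixture(mix, subjects, "T0"))
  pp <- colMeans(predict(plain, subjects))
  expect_lt(max(abs(pm - pp)), 0.03)
})

test_that("the utility-of-testing report is internally consistent", {
  cfg <- united_config(seed = 57)
  cc <- generate_case_control(cfg)
  pop <- apply_testing_cascade(generate_population(cfg))
  fit <- quiet(fit_mixture(pop, mode = "recalibration", cc = cc,
                           mcmc = mcmc_fast(seed = 57)))
  subjects <- as.data.frame(pop[1:20, raremix:::COVARIATE_ORDER])
  subjects$bmi <- pop$bmi[1:20]
  rep <- testing_utility_report(fit, subjects)
  expect_equal(nrow(rep), 20)
  # definitional identity: marginal = q * p1 + (1 - q) * p0, draw-wise
  br <- raremix:::mixture_branch_draws(fit, subjects)
  unk <- predict_mixture(fit, subjects, "unknown")
  expect_equal(unk, br$q * br$p1 + (1 - br$q) * br$p0, tolerance = 1e-12)
  expect_equal(rep$prob_mean, colMeans(unk), tolerance = 1e-12)
  expect_true(all(rep$q_mean >= 0 & rep$q_mean <= 1))
  # near-certain membership means testing is nearly uninformative
  expect_true(all(rep$swing >= 0))
  expect_true(all(rep$swing <= pmax(abs(rep$prob_if_consistent -
                                          rep$prob_mean),
                                    abs(rep$prob_if_inconsistent -
                                          rep$prob_mean)) + 1e-9))
  # subjects with a known status are refused
  known <- as.data.frame(pop[1:3, ])
  expect_error(testing_utility_report(fit, known), "unknown biomarker")
})
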
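## Non-mixture recalibration approaches.
##
## All fitters share the clinical-features linear predictor
##   logit(p) = b0 + b1*parent_affected + b2*age_at_recruitment + b3*hba1c
##              + b4*age_at_diagnosis + b5*sex
## and vague normal(0, 10) coefficient priors.

#' Odds / probability conversions and screening arithmetic
#'
#' Small exact helpers used throughout the recalibration pipeline:
#' pre-test probabilities from cohort counts, positive predictive values
#' from referral counts, and the odds scale conversions behind the
#' conversion-table recalibrator.
#'
#' @param p Probability in (0, 1).
#' @param o Odds (> 0).
#' @param n_pos,n_total Event and cohort counts.
#' @param n_true_pos,n_referred True-positive and referred counts.
#' @return Numeric scalar/vector.
#' @export
prob_to_odds <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("probability must be in (0, 1)")
  p / (1 - p)
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(o) {
  if (any(o < 0)) stop("odds must be non-negative")
  o / (1 + o)
}

#' @rdname prob_to_odds
#' @export
pretest_probability <- function(n_pos, n_total) {
  if (n_total <= 0 || n_pos < 0 || n_pos > n_total) stop("invalid counts")
  n_pos / n_total
}

#' @rdname prob_to_odds
#' @export
positive_predictive_value <- function(n_true_pos, n_referred) {
  if (n_referred <= 0 || n_true_pos < 0 || n_true_pos > n_referred) {
    stop("invalid counts")
  }
  n_true_pos / n_referred
}

check_covariates <- function(data, cols = COVARIATE_ORDER) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  }
  for (cn in cols) {
    if (any(is.na(data[[cn]]))) {
      stop("missing values in covariate: ", cn)
    }
  }
  invisible(TRUE)
}

# scenario semantics for population datasets:
#   a - assume every unlabeled (screened-out) subject is disease-negative
#   b - restrict to the genetically tested (t_indicator = 0) subset
apply_scenario <- function(pop, scenario = c("a", "b")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(pop, "subject_dataset"))
  if (attr(pop, "design") != "population") {
    stop("scenario filtering applies to population-design datasets")
  }
  if (scenario == "a") {
    n_imputed <- sum(is.na(pop$disease_label))
    if (n_imputed > 0) {
      message(sprintf(
        "scenario a: imputing %d unobserved labels as disease-negative (biomarker results inconsistent with disease)",
        n_imputed))
      pop$disease_label[is.na(pop$disease_label)] <- 0L
    }
    pop
  } else {
    if (any(is.na(pop$t_indicator))) {
      stop("scenario b requires t_indicator for every subject")
    }
    sub <- pop[pop$t_indicator == 0, ]
    if (any(is.na(sub$disease_label))) {
      stop("scenario b: tested subset contains unobserved labels")
    }
    message(sprintf("scenario b: restricting to %d biomarker-screened subjects",
                    nrow(sub)))
    sub
  }
}

#' Fit the case-control training model
#'
#' Bayesian logistic regression of disease status on the five clinical
#' features in the enriched case-control sample, with vague normal(0, 10)
#' coefficient priors. The fit records the training disease odds
#' (cases/controls) needed by the offset recalibrator.
#'
#' @param cc A case-control `subject_dataset` with complete labels.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A `training_fit`: posterior over the six coefficients plus
#'   training odds.
#' @export
fit_training_model <- function(cc, priors = prior_spec(),
                               mcmc = mcmc_config()) {
  stopifnot(inherits(cc, "subject_dataset"))
  if (attr(cc, "design") != "case_control") {
    stop("training model expects a case-control dataset")
  }
  if (any(is.na(cc$disease_label))) stop("training labels must be complete")
  n_cases <- sum(cc$disease_label == 1)
  n_controls <- sum(cc$disease_label == 0)
  if (n_cases == 0 || n_controls == 0) {
    stop("training data must contain both cases and controls")
  }
  check_covariates(cc)
  X <- risk_design(cc)
  post <- sample_posterior(spec_logistic(X, cc$disease_label), priors, mcmc)
  structure(list(posterior = post, covariates = COVARIATE_ORDER,
                 training_odds = n_cases / n_controls,
                 n_cases = n_cases, n_controls = n_controls),
            class = "training_fit")
}

coef_draws <- function(fit) {
  m <- as.matrix(fit$posterior)
  m[, seq_len(length(fit$covariates) + 1), drop = FALSE]
}

#' Per-draw predicted probabilities from the training model
#'
#' Applies each posterior coefficient draw to the supplied covariates,
#' giving a draws-by-subjects matrix of case-control-scale probabilities.
#'
#' @param fit A `training_fit`.
#' @param newdata Data frame with complete covariate columns.
#' @return Matrix of probabilities, one row per posterior draw.
#' @export
predict_training <- function(fit, newdata) {
  stopifnot(inherits(fit, "training_fit"))
  check_covariates(newdata)
  X <- risk_design(newdata)
  inv_logit(coef_draws(fit) %*% t(X))
}

#' @export
predict.training_fit <- function(object, newdata, ...) {
  predict_training(object, newdata)
}

#' Build a probability conversion table
#'
#' The conversion-table recalibrator of the original model development:
#' predicted case-control probabilities are banded (deciles by default), a
#' hypothetical "test" at each band's lower edge gives a sensitivity and
#' specificity on the training data, and the band's recalibrated output is
#' the post-test probability obtained from the positive likelihood ratio at
#' that threshold times the target-population prior odds. The first band's
#' output is the target prevalence itself, so no subject can be assigned a
#' recalibrated probability below the population prevalence (a known
#' limitation of the approach). Bands follow the half-open convention: the
#' first band is open, subsequent bands include their lower edge, and the
#' final band includes 1.
#'
#' @param fitted_probs Point (posterior-mean) probabilities on the training
#'   subjects.
#' @param labels Binary training labels.
#' @param band_edges Increasing band edges spanning 0 to 1 (default
#'   deciles).
#' @param target_prevalence Disease prevalence in the target population.
#' @return A `conversion_table`.
#' @export
build_conversion_table <- function(fitted_probs, labels,
                                   band_edges = seq(0, 1, by = 0.1),
                                   target_prevalence) {
  if (length(fitted_probs) != length(labels)) stop("length mismatch")
  if (any(is.na(labels))) stop("labels must be complete")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must be in (0, 1)")
  }
  edges <- sort(unique(band_edges))
  if (edges[1] != 0 || edges[length(edges)] != 1) {
    stop("band_edges must span 0 to 1")
  }
  k <- length(edges) - 1
  prior_odds <- prob_to_odds(target_prevalence)
  out <- numeric(k)
  infinite_lr <- logical(k)
  out[1] <- target_prevalence
  cases <- fitted_probs[labels == 1]
  controls <- fitted_probs[labels == 0]
  for (i in seq(2, k)) {
    thr <- edges[i]
    sens <- mean(cases > thr)
    fpr <- mean(controls > thr)
    if (fpr == 0) {
      out[i] <- 1
      infinite_lr[i] <- TRUE
    } else {
      out[i] <- odds_to_prob(sens / fpr * prior_odds)
    }
  }
  structure(list(bands = data.frame(lower = edges[-length(edges)],
                                    upper = edges[-1],
                                    output = out,
                                    infinite_lr = infinite_lr),
                 target_prevalence = target_prevalence),
            class = "conversion_table")
}

#' @export
print.conversion_table <- function(x, ...) {
  cat(sprintf("conversion_table (target prevalence %.4f)\n",
              x$target_prevalence))
  b <- x$bands
  lab <- sprintf("%s%.0f, %.0f%s", c("(", rep("[", nrow(b) - 1)),
                 b$lower * 100, b$upper * 100,
                 c(rep(")", nrow(b) - 1), "]"))
  print(data.frame(`case-control band (%)` = lab,
                   `recalibrated (%)` = round(b$output * 100, 1),
                   check.names = FALSE))
  invisible(x)
}

#' Map probabilities through a conversion table
#'
#' @param table A `conversion_table`.
#' @param p Probabilities in (0, 1].
#' @return Recalibrated probabilities (piecewise constant in `p`).
#' @export
apply_conversion <- function(table, p) {
  stopifnot(inherits(table, "conversion_table"))
  if (any(p <= 0 | p > 1)) stop("probabilities must lie in (0, 1]")
  lower <- table$bands$lower
  idx <- vapply(p, function(pp) 1L + sum(pp >= lower[-1]), integer(1))
  table$bands$output[idx]
}

#' Export / import a conversion table as CSV
#'
#' Two-column layout (band, recalibrated probability) matching the
#' published presentation.
#'
#' @param table A `conversion_table`.
#' @param path CSV path.
#' @return `write_conversion_table()` returns `path` invisibly.
#' @export
write_conversion_table <- function(table, path) {
  b <- table$bands
  utils::write.csv(data.frame(lower = b$lower, upper = b$upper,
                              output = b$output,
                              infinite_lr = b$infinite_lr),
                   path, row.names = FALSE)
  invisible(path)
}

#' Offset-recalibrated predictions
#'
#' Likelihood-ratio ("offset") updating: under the assumption that the
#' covariate-specific likelihood ratio is identical in the training and
#' target populations, the training linear predictor is shifted by
#' log(target disease odds) - log(training disease odds) on the log-odds
#' scale. The shift is constant, so subject rankings (and hence AUROC) are
#' identical to the training model's.
#'
#' @param fit A `training_fit`.
#' @param newdata Data frame with complete covariates.
#' @param odds_target Disease odds in the target population (> 0).
#' @param odds_train Disease odds in the training data; defaults to the
#'   odds recorded in the fit.
#' @return Matrix of per-draw probabilities (draws x subjects).
#' @export
albert_offset_predict <- function(fit, newdata, odds_target,
                                  odds_train = fit$training_odds) {
  stopifnot(inherits(fit, "training_fit"))
  if (odds_target <= 0 || odds_train <= 0) stop("odds must be positive")
  check_covariates(newdata)
  X <- risk_design(newdata)
  lp <- coef_draws(fit) %*% t(X) - log(odds_train) + log(odds_target)
  inv_logit(lp)
}

#' Re-estimate the risk model on the population cohort
#'
#' Fits a fresh Bayesian logistic regression of disease status on the
#' clinical features directly in the population-representative dataset,
#' ignoring the case-control data. Scenario "a" analyses all subjects,
#' explicitly imputing unobserved (screened-out) labels as
#' disease-negative; scenario "b" restricts to the genetically tested
#' (`t_indicator` = 0) subset.
#'
#' @param pop A population `subject_dataset`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param scenario "a" or "b".
#' @return A `reestimation_fit`.
#' @export
fit_reestimation <- function(pop, priors = prior_spec(),
                             mcmc = mcmc_config(), scenario = c("a", "b")) {
  scenario <- match.arg(scenario)
  dat <- apply_scenario(pop, scenario)
  if (sum(dat$disease_label == 1) == 0) {
    stop("no cases remain after scenario filtering")
  }
  check_covariates(dat)
  X <- risk_design(dat)
  post <- sample_posterior(spec_logistic(X, dat$disease_label), priors, mcmc)
  structure(list(posterior = post, covariates = COVARIATE_ORDER,
                 scenario = scenario, n_used = nrow(dat)),
            class = "reestimation_fit")
}

#' @export
predict.reestimation_fit <- function(object, newdata, ...) {
  check_covariates(newdata)
  X <- risk_design(newdata)
  inv_logit(coef_draws(object) %*% t(X))
}

#' Joint hierarchical recalibration
#'
#' Fits the case-control model and the shrinkage recalibration model as one
#' joint posterior: for every MCMC draw of the case-control coefficients,
#' each population subject's linear predictor z is recomputed and enters a
#' Bernoulli calibration likelihood with success probability
#' invlogit(gamma0 + gamma1 * z). This propagates training-model
#' uncertainty into the recalibration parameters; gamma0 = 0, gamma1 = 1
#' means no recalibration is needed. Priors: normal(0, 10) on gamma0,
#' normal(1, 10) on gamma1, normal(0, 10) on coefficients.
#'
#' `method = "plugin"` instead fixes z at the posterior-mean training
#' linear predictor and fits the two-parameter shrinkage model alone; its
#' gamma posteriors understate uncertainty and are provided for comparison
#' only.
#'
#' @param cc Case-control `subject_dataset`.
#' @param pop Population `subject_dataset`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param scenario "a" or "b".
#' @param method "joint" (default) or "plugin".
#' @return A `recal_fit` holding gamma draws paired with the case-control
#'   coefficient draws that generated them.
#' @export
fit_joint_recalibration <- function(cc, pop, priors = prior_spec(),
                                    mcmc = mcmc_config(),
                                    scenario = c("a", "b"),
                                    method = c("joint", "plugin")) {
  scenario <- match.arg(scenario)
  method <- match.arg(method)
  stopifnot(inherits(cc, "subject_dataset"))
  if (attr(cc, "design") != "case_control") {
    stop("cc must be a case-control dataset")
  }
  dat <- apply_scenario(pop, scenario)
  check_covariates(cc)
  check_covariates(dat)
  Xc <- risk_design(cc)
  Xu <- risk_design(dat)

  if (method == "joint") {
    post <- sample_posterior(
      spec_joint_recalibration(Xc, cc$disease_label, Xu, dat$disease_label),
      priors, mcmc)
    structure(list(posterior = post, covariates = COVARIATE_ORDER,
                   scenario = scenario, method = "joint",
                   n_calibration = nrow(dat)),
              class = "recal_fit")
  } else {
    tfit <- fit_training_model(cc, priors, mcmc)
    beta_hat <- colMeans(coef_draws(tfit))
    z <- as.vector(Xu %*% beta_hat)
    Xz <- cbind(intercept = 1, z = z)
    post <- sample_posterior(
      spec_logistic(Xz, dat$disease_label,
                    coef_prior_means = c(priors$gamma0_mean,
                                         priors$gamma1_mean)),
      priors, mcmc)
    structure(list(posterior = post, covariates = COVARIATE_ORDER,
                   scenario = scenario, method = "plugin",
                   beta_hat = beta_hat, n_calibration = nrow(dat)),
              class = "recal_fit")
  }
}

#' Posterior draws of the recalibration parameters
#'
#' @param fit A `recal_fit` or recalibration-mode `mixture_fit`.
#' @return Two-column matrix of (gamma0, gamma1) draws.
#' @export
gamma_draws <- function(fit) {
  m <- as.matrix(fit$posterior)
  if (inherits(fit, "recal_fit") && fit$method == "plugin") {
    out <- m[, 1:2, drop = FALSE]
  } else {
    out <- m[, c("gamma0", "gamma1"), drop = FALSE]
  }
  colnames(out) <- c("gamma0", "gamma1")
  out
}

#' @export
predict.recal_fit <- function(object, newdata, ...) {
  check_covariates(newdata)
  X <- risk_design(newdata)
  m <- as.matrix(object$posterior)
  if (object$method == "joint") {
    B <- m[, seq_len(length(object$covariates) + 1), drop = FALSE]
    g <- m[, c("gamma0", "gamma1"), drop = FALSE]
    z <- B %*% t(X)
  } else {
    g <- m[, 1:2, drop = FALSE]
    z_new <- as.vector(X %*% object$beta_hat)
    z <- matrix(z_new, nrow = nrow(g), ncol = nrow(X), byrow = TRUE)
  }
  inv_logit(g[, 1] + g[, 2] * z)
}
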
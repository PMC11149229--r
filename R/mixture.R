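## Hierarchical mixture model over biomarker groups.
##
## Subjects split on the composite screening indicator T (1 = C-peptide
## negative or antibody positive, biomarkers inconsistent with disease;
## 0 = C-peptide positive and antibody negative). The T = 1 branch has a
## single disease probability constrained by an informative Beta(2.2,
## 7361.3) prior; the T = 0 branch uses either re-estimation (fresh
## coefficients) or joint recalibration (shrinkage on the case-control
## linear predictor). A logistic membership model for T on clinical
## features (restricted cubic splines for the continuous ones) lets the
## model marginalise over missing biomarker status at prediction time.

T_CONTINUOUS <- c("bmi", "age_at_diagnosis", "age_at_recruitment")

t_model_knots <- function(data) {
  lapply(stats::setNames(T_CONTINUOUS, T_CONTINUOUS), function(v) {
    as.numeric(stats::quantile(data[[v]], c(0.1, 0.5, 0.9)))
  })
}

t_design <- function(data, knots) {
  cols <- list(intercept = rep(1, nrow(data)))
  for (v in T_CONTINUOUS) {
    b <- rcs_basis(data[[v]], knots[[v]])
    cols[[paste0(v, "_lin")]] <- b[, 1]
    cols[[paste0(v, "_rcs")]] <- b[, 2]
  }
  cols$parent_affected <- data$parent_affected
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit the biomarker mixture model
#'
#' Joint MCMC over all mixture components on a population cohort whose
#' screening indicator is known for every subject: the constrained-branch
#' disease probability (Beta-prior Bernoulli likelihood over T = 1
#' subjects, whose unobserved labels are explicitly treated as
#' disease-negative, mirroring the clinical argument that these biomarkers
#' rule the disease out), the unconstrained-branch model over T = 0
#' subjects (re-estimation or joint recalibration, with the case-control
#' linear predictor recomputed per draw in the latter), and the membership
#' model for T on BMI, age at diagnosis, age at recruitment (restricted
#' cubic splines, knots at the 10/50/90th percentiles) and parental
#' diabetes.
#'
#' @param pop Population `subject_dataset`; `t_indicator` known for all
#'   subjects, labels observed for all T = 0 subjects.
#' @param mode "reestimation" or "recalibration".
#' @param cc Case-control `subject_dataset`; required for recalibration
#'   mode.
#' @param priors A [prior_spec()]; `branch_alpha`/`branch_beta` set the
#'   informative prior on the constrained branch.
#' @param mcmc An [mcmc_config()].
#' @return A `mixture_fit`.
#' @export
fit_mixture <- function(pop, mode = c("recalibration", "reestimation"),
                        cc = NULL, priors = prior_spec(),
                        mcmc = mcmc_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "subject_dataset"))
  if (attr(pop, "design") != "population") {
    stop("mixture model expects a population dataset")
  }
  if (any(is.na(pop$t_indicator))) {
    stop("t_indicator must be known for every subject at fit time; ",
         "missing-biomarker handling is a prediction-time feature")
  }
  if (mode == "recalibration" && is.null(cc)) {
    stop("recalibration mode requires a case-control dataset")
  }
  check_covariates(pop)

  t1 <- pop[pop$t_indicator == 1, ]
  t0 <- pop[pop$t_indicator == 0, ]
  if (any(is.na(t0$disease_label))) {
    stop("all biomarker-screened (T = 0) subjects must have observed labels")
  }
  n_imputed <- sum(is.na(t1$disease_label))
  if (n_imputed > 0) {
    message(sprintf(
      "mixture fit: treating %d unobserved labels in the T = 1 branch as disease-negative",
      n_imputed))
  }
  lab1 <- t1$disease_label
  lab1[is.na(lab1)] <- 0L
  m1 <- sum(lab1 == 1)
  n1 <- length(lab1)

  knots <- t_model_knots(pop)
  Xt <- t_design(pop, knots)
  # a branch with no cases still has a proper posterior (vague but proper
  # priors); bootstrap replicates with few cases are retained and flagged
  # downstream rather than refused here
  Xu <- risk_design(t0)

  if (mode == "reestimation") {
    spec <- spec_mixture("reestimation", Xu, t0$disease_label, m1, n1,
                         Xt, pop$t_indicator)
  } else {
    stopifnot(inherits(cc, "subject_dataset"))
    if (attr(cc, "design") != "case_control") {
      stop("cc must be a case-control dataset")
    }
    check_covariates(cc)
    Xc <- risk_design(cc)
    spec <- spec_mixture("recalibration", Xu, t0$disease_label, m1, n1,
                         Xt, pop$t_indicator, Xc, cc$disease_label)
  }
  post <- sample_posterior(spec, priors, mcmc)
  structure(list(posterior = post, mode = mode, knots = knots,
                 covariates = COVARIATE_ORDER,
                 branch1_counts = c(m = m1, n = n1),
                 n_imputed = n_imputed,
                 n_branch0 = nrow(t0)),
            class = "mixture_fit")
}

mixture_branch_draws <- function(fit, newdata) {
  m <- as.matrix(fit$posterior)
  p1 <- m[, "p_branch1"]
  X <- risk_design(newdata)
  if (fit$mode == "reestimation") {
    B <- m[, grep("^betaU_", colnames(m)), drop = FALSE]
    p0 <- inv_logit(B %*% t(X))
  } else {
    B <- m[, grep("^betaC_", colnames(m)), drop = FALSE]
    z <- B %*% t(X)
    p0 <- inv_logit(m[, "gamma0"] + m[, "gamma1"] * z)
  }
  Bt <- m[, grep("^betaT_", colnames(m)), drop = FALSE]
  Xt <- t_design(newdata, fit$knots)
  q <- inv_logit(Bt %*% t(Xt))
  list(p1 = p1, p0 = p0, q = q)
}

#' Predict disease probability from the mixture model
#'
#' For subjects with known biomarker status the prediction is the matching
#' branch: the constrained posterior probability for T = 1, the
#' covariate-model branch for T = 0. For subjects with unknown status the
#' prediction marginalises over the latent status draw-wise:
#' q * p1 + (1 - q) * p0, with q the subject's membership probability from
#' the T-model, so the full posterior uncertainty of the missing biomarker
#' propagates into the prediction.
#'
#' @param fit A `mixture_fit`.
#' @param newdata Data frame with complete covariates (including the
#'   T-model covariates when `biomarker_status = "unknown"`).
#' @param biomarker_status "T1", "T0" or "unknown" (applies to all supplied
#'   subjects).
#' @param q_override Optional fixed membership probability replacing the
#'   T-model draws (used for degenerate checks).
#' @return Matrix of per-draw probabilities (draws x subjects).
#' @export
predict_mixture <- function(fit, newdata,
                            biomarker_status = c("unknown", "T0", "T1"),
                            q_override = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  biomarker_status <- match.arg(biomarker_status)
  check_covariates(newdata)
  n <- nrow(newdata)
  if (biomarker_status == "unknown") {
    needed <- c(T_CONTINUOUS, "parent_affected")
    for (cn in needed) {
      if (!cn %in% names(newdata) || any(is.na(newdata[[cn]]))) {
        stop("missing T-model covariate with unknown biomarker status: ", cn)
      }
    }
  }
  br <- mixture_branch_draws(fit, newdata)
  if (biomarker_status == "T1") {
    return(matrix(br$p1, nrow = length(br$p1), ncol = n))
  }
  if (biomarker_status == "T0") {
    return(br$p0)
  }
  q <- if (is.null(q_override)) br$q else {
    matrix(q_override, nrow = length(br$p1), ncol = n)
  }
  q * br$p1 + (1 - q) * br$p0
}

#' Utility-of-testing report for untested subjects
#'
#' For subjects whose biomarker status is unknown, reports the
#' marginalised disease probability alongside the two conditional
#' predictions (what the probability would be if biomarker testing came
#' back inconsistent, T = 1, or consistent, T = 0, with disease) and the
#' posterior membership probability q, making the probability swing a
#' biomarker test could produce explicit for referral decisions.
#'
#' @param fit A `mixture_fit`.
#' @param newdata Data frame of untested subjects; if a `t_indicator`
#'   column is present it must be missing for every row.
#' @return Data frame with one row per subject: posterior mean and 95%
#'   interval of the marginal prediction, the conditional predictions, q,
#'   and the expected absolute probability swing from testing.
#' @export
testing_utility_report <- function(fit, newdata) {
  stopifnot(inherits(fit, "mixture_fit"))
  if ("t_indicator" %in% names(newdata) &&
      any(!is.na(newdata$t_indicator))) {
    stop("testing utility report is for subjects with unknown biomarker status")
  }
  check_covariates(newdata)
  br <- mixture_branch_draws(fit, newdata)
  unk <- br$q * br$p1 + (1 - br$q) * br$p0
  n <- nrow(newdata)
  p1m <- mean(br$p1)
  data.frame(
    prob_mean = colMeans(unk),
    prob_lo = apply(unk, 2, stats::quantile, 0.025),
    prob_hi = apply(unk, 2, stats::quantile, 0.975),
    prob_if_inconsistent = rep(p1m, n),
    prob_if_consistent = colMeans(br$p0),
    q_mean = colMeans(br$q),
    swing = colMeans(br$q * abs(br$p1 - unk) +
                       (1 - br$q) * abs(br$p0 - unk)),
    row.names = NULL)
}
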
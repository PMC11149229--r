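## Synthetic cohort generation
##
## A single logistic generating model produces both study designs: the
## population cohort is a random sample from the model, and the case-control
## sample is drawn (cases and controls separately, without replacement) from
## a large latent population generated by the same model. Sampling on the
## outcome preserves the covariate-specific likelihood ratio between the two
## designs, which is exactly the assumption the offset recalibrator relies
## on, so assumption-violation experiments must introduce the violation
## explicitly via covariate_shift_variant().

COVARIATE_ORDER <- c("parent_affected", "age_at_recruitment", "hba1c",
                     "age_at_diagnosis", "sex")

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the structure of the study system: a case-control
#' sample of 177 cases and 278 controls (40% enrichment), a
#' population cohort of 1171 insulin-treated subjects with 0.6% disease
#' prevalence, and a biomarker-testing cascade in which only
#' C-peptide-positive, antibody-negative subjects receive the gold-standard
#' genetic test. Non-intercept generating coefficients default to the
#' published clinical-features model (parent affected 3.22, age at
#' recruitment -0.09, HbA1c -0.68, age at diagnosis 0.10, female sex 1.35);
#' the intercept is tuned at generation time so that the marginal prevalence
#' matches `prevalence_target`.
#'
#' @param n_cases,n_controls Case-control sample sizes.
#' @param n_population Population cohort size.
#' @param true_coefficients Named log-odds effects for the five covariates
#'   (parent_affected, age_at_recruitment, hba1c, age_at_diagnosis, sex).
#' @param prevalence_target Marginal disease prevalence in (0, 0.5).
#' @param biomarker_conditional_probs Named probabilities
#'   `cpep_pos_disease`, `cpep_pos_healthy`, `ab_pos_disease`,
#'   `ab_pos_healthy`: P(C+ | disease status) and P(A+ | disease status),
#'   independent given status. Defaults approximately reproduce the target
#'   cohort's realized biomarker composition (924 C-, 151 C+A+, 96 C+A- of
#'   1171) at 0.6% prevalence.
#' @param covariate_distributions Per-covariate family parameters; see
#'   defaults in the function signature.
#' @param seed Integer seed; expands deterministically to per-stage
#'   substreams.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_cases = 177L, n_controls = 278L, n_population = 1171L,
    true_coefficients = c(parent_affected = 3.22, age_at_recruitment = -0.09,
                          hba1c = -0.68, age_at_diagnosis = 0.10,
                          sex = 1.35),
    prevalence_target = 0.006,
    biomarker_conditional_probs = c(cpep_pos_disease = 0.99,
                                    cpep_pos_healthy = 0.20,
                                    ab_pos_disease = 0.01,
                                    ab_pos_healthy = 0.60),
    covariate_distributions = list(
      sex = list(prob = 0.5),
      parent_affected = list(prob = 0.25),
      age_at_diagnosis = list(mean = 16, sd = 7, lower = 1, upper = 35),
      recruitment_gap = list(shape = 2, scale = 5),
      bmi = list(meanlog = log(24), sdlog = 0.15),
      hba1c = list(mean = 8.5, sd = 1.5, lower = 4, upper = 16)),
    seed = 1L) {
  if (n_cases < 0 || n_controls <= 0 || n_population <= 0) {
    stop("cohort sizes must be positive")
  }
  if (prevalence_target <= 0 || prevalence_target >= 0.5) {
    stop("prevalence_target must lie in (0, 0.5): rare-disease regime")
  }
  bp <- biomarker_conditional_probs
  need <- c("cpep_pos_disease", "cpep_pos_healthy", "ab_pos_disease",
            "ab_pos_healthy")
  if (!all(need %in% names(bp)) || any(bp < 0) || any(bp > 1)) {
    stop("biomarker_conditional_probs must name ", paste(need, collapse = ", "),
         " with values in [0, 1]")
  }
  if (!all(COVARIATE_ORDER %in% names(true_coefficients))) {
    stop("true_coefficients must name: ", paste(COVARIATE_ORDER, collapse = ", "))
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_population = as.integer(n_population),
                 true_coefficients = true_coefficients[COVARIATE_ORDER],
                 prevalence_target = prevalence_target,
                 biomarker_conditional_probs = bp[need],
                 covariate_distributions = covariate_distributions,
                 seed = as.integer(seed)),
            class = "generator_config")
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

sample_covariates <- function(n, dists) {
  aad <- rtruncnorm(n, dists$age_at_diagnosis$mean,
                    dists$age_at_diagnosis$sd,
                    dists$age_at_diagnosis$lower,
                    dists$age_at_diagnosis$upper)
  gap <- stats::rgamma(n, shape = dists$recruitment_gap$shape,
                       scale = dists$recruitment_gap$scale)
  data.frame(
    sex = stats::rbinom(n, 1, dists$sex$prob),
    parent_affected = stats::rbinom(n, 1, dists$parent_affected$prob),
    age_at_diagnosis = aad,
    age_at_recruitment = aad + gap,
    bmi = stats::rlnorm(n, dists$bmi$meanlog, dists$bmi$sdlog),
    hba1c = rtruncnorm(n, dists$hba1c$mean, dists$hba1c$sd,
                       dists$hba1c$lower, dists$hba1c$upper))
}

# risk-model design matrix in the fixed covariate order, leading intercept
risk_design <- function(data) {
  X <- cbind(1,
             data$parent_affected,
             data$age_at_recruitment,
             data$hba1c,
             data$age_at_diagnosis,
             data$sex)
  colnames(X) <- c("intercept", COVARIATE_ORDER)
  X
}

# tune the generating intercept by bisection so the expected prevalence over
# the sampled covariates hits the target within tol
tune_intercept <- function(X_nointercept, coefs, target, tol = 1e-4) {
  lp0 <- as.vector(X_nointercept %*% coefs)
  f <- function(b0) mean(inv_logit(b0 + lp0)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("prevalence_target unattainable given coefficient magnitudes")
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f((lo + hi) / 2)) < tol / 10) break
  }
  b0 <- (lo + hi) / 2
  if (abs(f(b0)) > tol) stop("intercept bisection failed to reach tolerance")
  b0
}

derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

# draw one latent cohort (covariates, labels, biomarkers) from the model
draw_cohort <- function(n, config, seed) {
  set.seed(seed)
  cov <- sample_covariates(n, config$covariate_distributions)
  X <- risk_design(cov)
  b0 <- tune_intercept(X[, -1, drop = FALSE], config$true_coefficients,
                       config$prevalence_target)
  p <- inv_logit(b0 + as.vector(X[, -1, drop = FALSE] %*%
                                  config$true_coefficients))
  label <- stats::rbinom(n, 1, p)
  bp <- config$biomarker_conditional_probs
  p_c <- ifelse(label == 1, bp["cpep_pos_disease"], bp["cpep_pos_healthy"])
  p_a <- ifelse(label == 1, bp["ab_pos_disease"], bp["ab_pos_healthy"])
  cpep <- stats::rbinom(n, 1, p_c)
  ab <- stats::rbinom(n, 1, p_a)
  cov$cpep_status <- ifelse(cpep == 1, "positive", "negative")
  cov$antibody_status <- ifelse(ab == 1, "positive", "negative")
  cov$t_indicator <- as.integer(cpep == 0 | ab == 1)
  cov$disease_label <- label
  attr(cov, "intercept") <- b0
  cov
}

#' Generate a population-representative cohort
#'
#' Samples covariates, tunes the generating intercept by bisection so the
#' expected prevalence over the sampled covariates matches
#' `prevalence_target` (tolerance 1e-4), draws disease labels from the
#' logistic model and biomarker statuses from their disease-conditional
#' probabilities, and derives the composite screening indicator
#' (`t_indicator` = 1 for C-negative or antibody-positive subjects). All
#' labels are initially observed; use [apply_testing_cascade()] to emulate
#' the screening strategy under which only C+A- subjects are genetically
#' tested.
#'
#' @param config A [generator_config()].
#' @return A `subject_dataset` with `design = "population"`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- draw_cohort(config$n_population, config,
                        derive_seed(config$seed, 1))
  out <- new_dataset(cohort, design = "population",
                     provenance = sprintf(
                       "synthetic population: n=%d, prevalence_target=%g, seed=%d, tuned_intercept=%.4f",
                       config$n_population, config$prevalence_target,
                       config$seed, attr(cohort, "intercept")))
  attr(out, "generating_intercept") <- attr(cohort, "intercept")
  out
}

#' Generate an enriched case-control sample
#'
#' Draws a large latent population from the same generating model as
#' [generate_population()], then samples `n_cases` diseased and
#' `n_controls` non-diseased subjects without replacement. Because selection
#' acts only on the outcome, the covariate-specific likelihood ratio is the
#' same in both designs by construction. Biomarker columns are blanked (the
#' case-control study predates biomarker testing).
#'
#' @param config A [generator_config()].
#' @param pool_multiplier Size of the latent pool relative to the minimum
#'   needed in expectation; raise it if case yield is borderline.
#' @return A `subject_dataset` with `design = "case_control"`.
#' @export
generate_case_control <- function(config, pool_multiplier = 2) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_cases <= 0) stop("n_cases must be positive")
  prev <- config$prevalence_target
  n_pool <- ceiling(pool_multiplier *
                      max(config$n_cases / prev,
                          config$n_controls / (1 - prev)))
  pool <- draw_cohort(n_pool, config, derive_seed(config$seed, 2))
  cases <- which(pool$disease_label == 1)
  controls <- which(pool$disease_label == 0)
  if (length(cases) < config$n_cases) {
    stop(sprintf("latent pool yielded %d cases, need %d; increase pool_multiplier",
                 length(cases), config$n_cases))
  }
  if (length(controls) < config$n_controls) {
    stop("latent pool yielded too few controls")
  }
  idx <- c(sample(cases, config$n_cases),
           sample(controls, config$n_controls))
  cc <- pool[idx, , drop = FALSE]
  rownames(cc) <- NULL
  cc$cpep_status <- NA_character_
  cc$antibody_status <- NA_character_
  cc$t_indicator <- NA_integer_
  out <- new_dataset(cc, design = "case_control",
                     provenance = sprintf(
                       "synthetic case-control: %d cases / %d controls from latent pool n=%d, seed=%d",
                       config$n_cases, config$n_controls, n_pool,
                       config$seed))
  attr(out, "generating_intercept") <- attr(pool, "intercept")
  out
}

#' Apply the biomarker testing cascade
#'
#' Emulates the screening strategy of the population study: subjects whose
#' biomarkers are inconsistent with the disease (`t_indicator` = 1, i.e.
#' C-peptide negative or antibody positive) were never referred for the
#' gold-standard genetic test, so their disease labels become unobserved.
#' Covariates, biomarkers and record count are untouched.
#'
#' @param dataset A population-design `subject_dataset` with biomarkers
#'   populated.
#' @return The dataset with `disease_label` set to `NA` where
#'   `t_indicator` = 1.
#' @export
apply_testing_cascade <- function(dataset) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (attr(dataset, "design") != "population") {
    stop("testing cascade applies only to population-design datasets")
  }
  if (any(is.na(dataset$t_indicator))) {
    stop("t_indicator must be known for every subject")
  }
  dataset$disease_label[dataset$t_indicator == 1] <- NA_integer_
  attr(dataset, "provenance") <- paste0(attr(dataset, "provenance"),
                                        "; testing cascade applied")
  dataset
}

#' Build a covariate-shifted variant of a generator configuration
#'
#' Produces a training/population configuration pair whose
#' covariate-specific likelihood ratios differ, used to study recalibrator
#' behaviour when the offset method's constant-likelihood-ratio assumption
#' fails. A `coefficient_scale` entry multiplies the named covariate's
#' generating coefficient in the population configuration only; a
#' `distribution` entry replaces that covariate's sampling parameters.
#'
#' @param config A [generator_config()].
#' @param shift_spec A list with element `covariate` (one of the model
#'   covariates) and at least one of `coefficient_scale` (numeric) or
#'   `distribution` (replacement parameter list).
#' @return A list with elements `training` (unchanged config) and
#'   `population` (shifted config).
#' @export
covariate_shift_variant <- function(config, shift_spec) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(shift_spec) || length(shift_spec) == 0) {
    stop("shift_spec must not be empty")
  }
  covar <- shift_spec$covariate
  if (is.null(covar) || !covar %in% COVARIATE_ORDER) {
    stop("shift_spec$covariate must be one of: ",
         paste(COVARIATE_ORDER, collapse = ", "))
  }
  if (is.null(shift_spec$coefficient_scale) &&
      is.null(shift_spec$distribution)) {
    stop("shift_spec must supply coefficient_scale and/or distribution")
  }
  shifted <- config
  if (!is.null(shift_spec$coefficient_scale)) {
    shifted$true_coefficients[covar] <-
      shifted$true_coefficients[covar] * shift_spec$coefficient_scale
  }
  if (!is.null(shift_spec$distribution)) {
    shifted$covariate_distributions[[covar]] <- shift_spec$distribution
  }
  list(training = config, population = shifted)
}

## ---- dataset container ---------------------------------------------------

DATASET_COLUMNS <- c("sex", "parent_affected", "age_at_diagnosis",
                     "age_at_recruitment", "bmi", "hba1c", "cpep_status",
                     "antibody_status", "t_indicator", "disease_label")

#' Construct a subject-level dataset
#'
#' A `subject_dataset` is a data frame of one row per subject with the
#' standard column set (sex, parent_affected, age_at_diagnosis,
#' age_at_recruitment, bmi, hba1c, cpep_status, antibody_status,
#' t_indicator, disease_label) plus `design` ("case_control" or
#' "population") and free-text `provenance` attributes. Invariants enforced:
#' recruitment age is never below diagnosis age; `t_indicator` agrees with
#' the biomarker statuses where both are known; unlabeled subjects must have
#' a known screening indicator (only screened-out subjects lack labels);
#' case-control datasets carry complete labels and no biomarker data.
#'
#' @param data A data frame with the standard columns.
#' @param design "case_control" or "population".
#' @param provenance Free-text description of how the data arose.
#' @return A `subject_dataset`.
#' @export
new_dataset <- function(data, design = c("population", "case_control"),
                        provenance = "unspecified") {
  design <- match.arg(design)
  missing_cols <- setdiff(DATASET_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[DATASET_COLUMNS]
  rownames(data) <- NULL
  bad_age <- which(data$age_at_recruitment < data$age_at_diagnosis)
  if (length(bad_age)) {
    stop("age_at_recruitment < age_at_diagnosis at rows: ",
         paste(utils::head(bad_age, 10), collapse = ", "))
  }
  bad_h <- which(!is.na(data$hba1c) & data$hba1c <= 0)
  if (length(bad_h)) {
    stop("non-positive HbA1c at rows: ",
         paste(utils::head(bad_h, 10), collapse = ", "))
  }
  both <- !is.na(data$cpep_status) & !is.na(data$antibody_status)
  if (any(both)) {
    t_expect <- as.integer(data$cpep_status[both] == "negative" |
                             data$antibody_status[both] == "positive")
    mism <- which(!is.na(data$t_indicator[both]) &
                    data$t_indicator[both] != t_expect)
    if (length(mism)) {
      stop("t_indicator inconsistent with biomarker statuses at rows: ",
           paste(utils::head(which(both)[mism], 10), collapse = ", "))
    }
  }
  unlab <- is.na(data$disease_label)
  if (any(unlab & is.na(data$t_indicator))) {
    stop("subjects with unobserved disease labels must have known t_indicator")
  }
  if (design == "case_control") {
    if (any(unlab)) stop("case_control datasets must have complete labels")
    if (any(!is.na(data$cpep_status)) || any(!is.na(data$antibody_status))) {
      stop("case_control datasets carry no biomarker data")
    }
  }
  structure(data, design = design, provenance = provenance,
            class = c("subject_dataset", "data.frame"))
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset (%s): %d subjects, %d labeled, %d cases\n",
              attr(x, "design"), nrow(x), sum(!is.na(x$disease_label)),
              sum(x$disease_label == 1, na.rm = TRUE)))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

# keep attributes when subsetting rows
#' @export
`[.subject_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), DATASET_COLUMNS)) {
    attr(out, "design") <- attr(x, "design")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("subject_dataset", "data.frame")
  }
  out
}
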
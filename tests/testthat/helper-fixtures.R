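# Shared fixtures: configurations, quiet wrappers, and a degenerate
# training fit pinned at known coefficients (for checks that isolate the
# recalibration arithmetic from coefficient-estimation noise).

# study-structure defaults (case-control 177/278, population 1171 at 0.6%)
united_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, ...)
}

# matched-prevalence configuration: the population shares the case-control
# case fraction, so the two designs follow one identical logistic model and
# no recalibration is needed (gamma0 = 0, gamma1 = 1)
matched_config <- function(n_population = 20000, seed = 1L, ...) {
  generator_config(n_population = n_population,
                   prevalence_target = 177 / 455, seed = seed, ...)
}

mcmc_fast <- function(seed = 1L, n_chains = 2, n_iterations = 6000,
                      n_burnin = 2500, ...) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              n_burnin = n_burnin, seed = seed, ...)
}

mcmc_recal <- function(seed = 1L) {
  mcmc_config(n_chains = 2, n_iterations = 15000, n_burnin = 7500,
              seed = seed)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a training fit whose posterior is a point mass (tiny jitter for variance
# computations) at given natural-scale coefficients
pinned_training_fit <- function(coefs, training_odds, n_draws = 50) {
  d <- length(coefs)
  draws <- array(rep(coefs, each = n_draws * 2), dim = c(n_draws, 2, d),
                 dimnames = list(NULL, NULL, names(coefs)))
  post <- structure(list(draws = draws,
                         parameters = names(coefs),
                         rhat = stats::setNames(rep(1, d), names(coefs)),
                         accept_rate = c(1, 1),
                         metadata = list(model = "pinned")),
                    class = "posterior_samples")
  structure(list(posterior = post,
                 covariates = raremix:::COVARIATE_ORDER,
                 training_odds = training_odds,
                 n_cases = NA_integer_, n_controls = NA_integer_),
            class = "training_fit")
}

# generating coefficients of a configuration, with the intercept the
# generator tuned for a given dataset
generating_coefficients <- function(dataset, config) {
  c(intercept = attr(dataset, "generating_intercept"),
    config$true_coefficients)
}
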
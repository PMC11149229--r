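#' Log-odds and inverse-logit transforms
#'
#' `logit()` maps a probability in (0, 1) to the log-odds scale;
#' `inv_logit()` is its inverse. `inv_logit()` is computed in a numerically
#' stable form so that finite linear predictors never return exactly 0 or 1
#' until they exceed the double-precision overflow guard (|x| > 700).
#'
#' @param p Numeric vector of probabilities, strictly inside (0, 1).
#' @param x Numeric vector of log-odds (any finite value).
#' @return Numeric vector: log-odds for `logit()`, probabilities for
#'   `inv_logit()`.
#' @examples
#' inv_logit(0)          # 0.5
#' logit(inv_logit(-2))  # -2
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1)")
  }
  log(p) - log1p(-p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  if (any(!is.finite(x))) stop("inv_logit() requires finite input")
  x <- pmin(pmax(x, -700), 700)
  p <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  # keep finite linear predictors away from exactly 1 (largest double < 1)
  pmin(p, 1 - 2^-53)
}

#' Restricted cubic spline basis with three knots
#'
#' Returns the two-column truncated-power basis used to model continuous
#' covariates flexibly while forcing linearity beyond the boundary knots:
#' column 1 is the covariate itself, column 2 the restricted cubic term
#' (Harrell scaling, divided by the squared knot span), whose second
#' derivative vanishes outside `[knots[1], knots[3]]`.
#'
#' @param x Numeric vector (finite).
#' @param knots Three strictly increasing numeric knot locations. Defaults
#'   to the 10th, 50th and 90th percentiles of `x`.
#' @return Numeric matrix with columns `lin` and `rcs1`.
#' @export
rcs_basis <- function(x, knots = stats::quantile(x, c(0.1, 0.5, 0.9))) {
  if (any(!is.finite(x))) stop("rcs_basis() requires finite x")
  knots <- as.numeric(knots)
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop("knots must be 3 strictly increasing values")
  }
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  nl <- (cube(x - t1) -
           cube(x - t2) * (t3 - t1) / (t3 - t2) +
           cube(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  out <- cbind(lin = x, rcs1 = nl)
  attr(out, "knots") <- knots
  out
}

#' Prior specification for all fitters
#'
#' Vague independent normal(0, 10) priors on regression coefficients, a
#' normal(0, 10) prior on the recalibration intercept, a normal(1, 10) prior
#' on the recalibration slope (centred at "no recalibration needed"), and an
#' informative Beta(2.2, 7361.3) prior on the probability of disease in the
#' biomarker-inconsistent branch of the mixture model. The Beta parameters
#' encode external evidence that disease is extremely rare among subjects
#' whose biomarker results argue against it (prior mean about 3e-4).
#'
#' @param regression_mean,regression_sd Normal prior for regression
#'   coefficients.
#' @param gamma0_mean,gamma0_sd Normal prior for the recalibration intercept.
#' @param gamma1_mean,gamma1_sd Normal prior for the recalibration slope.
#' @param branch_alpha,branch_beta Beta prior for the constrained branch
#'   probability.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(regression_mean = 0, regression_sd = 10,
                       gamma0_mean = 0, gamma0_sd = 10,
                       gamma1_mean = 1, gamma1_sd = 10,
                       branch_alpha = 2.2, branch_beta = 7361.3) {
  sds <- c(regression_sd, gamma0_sd, gamma1_sd)
  if (any(sds <= 0)) stop("prior sds must be positive")
  if (branch_alpha <= 0 || branch_beta <= 0) {
    stop("Beta prior parameters must be positive")
  }
  structure(list(regression_mean = regression_mean,
                 regression_sd = regression_sd,
                 gamma0_mean = gamma0_mean, gamma0_sd = gamma0_sd,
                 gamma1_mean = gamma1_mean, gamma1_sd = gamma1_sd,
                 branch_alpha = branch_alpha, branch_beta = branch_beta),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Desk-scale defaults are 4 chains of 20,000 iterations with the first
#' 10,000 discarded; `full_scale = TRUE` switches to 4 chains of 500,000
#' iterations with 300,000 burn-in for final production fits. The simple
#' generalised-linear posteriors targeted here mix quickly, so the scaled
#' defaults give effectively converged chains (checked by split R-hat).
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iterations Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain (< n_iterations).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; all chain randomness derives from it.
#' @param rhat_threshold Split R-hat above which a convergence warning (not
#'   an error) is raised.
#' @param full_scale Use the production-scale 500k/300k settings.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 20000, n_burnin = 10000,
                        thin = 1, seed = 1L, rhat_threshold = 1.01,
                        full_scale = FALSE) {
  if (isTRUE(full_scale)) {
    n_iterations <- 500000
    n_burnin <- 300000
  }
  if (n_chains < 2) stop("n_chains must be >= 2")
  if (n_burnin >= n_iterations) stop("n_burnin must be < n_iterations")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Computes the split R-hat statistic: each chain is halved, and the ratio
#' of pooled to within-chain variance is formed across the resulting
#' half-chains. Values near 1 indicate mixing. When every half-chain has
#' zero internal variance the statistic is defined as 1 and flagged as
#' degenerate (attribute `degenerate`).
#'
#' @param draws A matrix with one column per chain (iterations in rows), or
#'   a list of equal-length numeric vectors.
#' @return Numeric scalar with attribute `degenerate` (logical).
#' @export
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("rhat requires >= 2 chains")
  if (nrow(draws) < 4) stop("rhat requires >= 4 draws per chain")
  half <- floor(nrow(draws) / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[seq(nrow(draws) - half + 1, nrow(draws)), ,
                        drop = FALSE])
  m <- colMeans(splits)
  v <- apply(splits, 2, stats::var)
  W <- mean(v)
  if (W == 0) {
    return(structure(1, degenerate = TRUE))
  }
  n <- half
  B_over_n <- stats::var(m)
  var_plus <- (n - 1) / n * W + B_over_n
  # values below 1 carry no convergence information; floor at 1
  structure(max(1, sqrt(var_plus / W)), degenerate = FALSE)
}

## ---- model specifications ------------------------------------------------

# Each spec describes one posterior for the block sampler. Design matrices
# include an explicit leading intercept column of ones.

spec_logistic <- function(X, y, coef_prior_means = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (any(!y %in% c(0, 1))) stop("y must be binary 0/1 with no missing values")
  structure(list(type = "logistic", X = X, y = as.numeric(y),
                 coef_prior_means = coef_prior_means),
            class = "model_spec")
}

spec_beta_bernoulli <- function(m, n) {
  if (m < 0 || n <= 0 || m > n) stop("need 0 <= m <= n, n > 0")
  structure(list(type = "beta_bernoulli", m = m, n = n), class = "model_spec")
}

spec_joint_recalibration <- function(Xc, yc, Xu, yu) {
  stopifnot(is.matrix(Xc), is.matrix(Xu), ncol(Xc) == ncol(Xu))
  structure(list(type = "joint_recalibration", Xc = Xc, yc = as.numeric(yc),
                 Xu = Xu, yu = as.numeric(yu)),
            class = "model_spec")
}

spec_mixture <- function(mode, Xu, yu, m1, n1, Xt, yt, Xc = NULL, yc = NULL) {
  mode <- match.arg(mode, c("reestimation", "recalibration"))
  if (mode == "recalibration" && is.null(Xc)) {
    stop("recalibration mode requires case-control data")
  }
  structure(list(type = "mixture", mode = mode, Xu = Xu, yu = as.numeric(yu),
                 m1 = m1, n1 = n1, Xt = Xt, yt = as.numeric(yt),
                 Xc = Xc, yc = if (is.null(yc)) NULL else as.numeric(yc)),
            class = "model_spec")
}

# center/scale the non-intercept columns of a design matrix; returns the
# standardized matrix plus the affine map needed to put coefficients back on
# the natural scale
standardize_design <- function(X, center = NULL, scale = NULL) {
  p <- ncol(X)
  if (is.null(center)) {
    center <- c(0, colMeans(X[, -1, drop = FALSE]))
    scale <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- X
  for (j in seq(2, p)) Xs[, j] <- (X[, j] - center[j]) / scale[j]
  list(X = Xs, center = center, scale = scale)
}

# map standardized-scale coefficient draws (rows) back to the natural scale
destandardize_coefs <- function(B, center, scale) {
  p <- ncol(B)
  out <- B
  for (j in seq(2, p)) out[, j] <- B[, j] / scale[j]
  out[, 1] <- B[, 1] -
    out[, -1, drop = FALSE] %*% matrix(center[-1], ncol = 1)
  out
}

# internal: assemble sampler arguments for a given spec
prepare_spec <- function(spec, priors) {
  empty_m <- matrix(0, 0, 1)
  empty_v <- numeric(0)
  args <- list(Xc = empty_m, yc = empty_v, use_cc = FALSE,
               Xu = empty_m, yu = empty_v, pop_mode = 0L,
               use_b1 = FALSE, m1 = 0, n1 = 0,
               a1 = priors$branch_alpha, b1 = priors$branch_beta,
               Xt = empty_m, yt = empty_v, use_t = FALSE)
  reg_m <- priors$regression_mean
  reg_s <- priors$regression_sd
  par_names <- character(0)
  prior_mean <- numeric(0)
  prior_sd <- numeric(0)
  init <- numeric(0)
  std <- list()

  if (spec$type == "logistic") {
    s <- standardize_design(spec$X)
    args$Xu <- s$X; args$yu <- spec$y; args$pop_mode <- 1L
    pm <- rep(reg_m, ncol(s$X))
    if (!is.null(spec$coef_prior_means)) pm <- spec$coef_prior_means
    par_names <- colnames(spec$X)
    prior_mean <- pm
    prior_sd <- rep(reg_s, ncol(s$X))
    init <- rep(0, ncol(s$X))
    std$u <- s
  } else if (spec$type == "beta_bernoulli") {
    args$use_b1 <- TRUE; args$m1 <- spec$m; args$n1 <- spec$n
    par_names <- "p"
    prior_mean <- 0; prior_sd <- 1   # unused for the branch logit
    init <- logit(priors$branch_alpha /
                    (priors$branch_alpha + priors$branch_beta))
  } else if (spec$type == "joint_recalibration") {
    s <- standardize_design(spec$Xc)
    su <- standardize_design(spec$Xu, s$center, s$scale)
    args$Xc <- s$X; args$yc <- spec$yc; args$use_cc <- TRUE
    args$Xu <- su$X; args$yu <- spec$yu; args$pop_mode <- 2L
    par_names <- c(paste0("betaC_", colnames(spec$Xc)), "gamma0", "gamma1")
    prior_mean <- c(rep(reg_m, ncol(s$X)), priors$gamma0_mean,
                    priors$gamma1_mean)
    prior_sd <- c(rep(reg_s, ncol(s$X)), priors$gamma0_sd, priors$gamma1_sd)
    init <- c(rep(0, ncol(s$X)), 0, 1)
    std$c <- s
  } else if (spec$type == "mixture") {
    st <- standardize_design(spec$Xt)
    args$Xt <- st$X; args$yt <- spec$yt; args$use_t <- TRUE
    args$use_b1 <- TRUE; args$m1 <- spec$m1; args$n1 <- spec$n1
    std$t <- st
    if (spec$mode == "reestimation") {
      su <- standardize_design(spec$Xu)
      args$Xu <- su$X; args$yu <- spec$yu; args$pop_mode <- 1L
      std$u <- su
      par_names <- c(paste0("betaU_", colnames(spec$Xu)), "p_branch1",
                     paste0("betaT_", colnames(spec$Xt)))
      prior_mean <- c(rep(reg_m, ncol(su$X)), 0, rep(reg_m, ncol(st$X)))
      prior_sd <- c(rep(reg_s, ncol(su$X)), 1, rep(reg_s, ncol(st$X)))
      init <- c(rep(0, ncol(su$X)),
                logit(priors$branch_alpha /
                        (priors$branch_alpha + priors$branch_beta)),
                rep(0, ncol(st$X)))
    } else {
      sc <- standardize_design(spec$Xc)
      su <- standardize_design(spec$Xu, sc$center, sc$scale)
      args$Xc <- sc$X; args$yc <- spec$yc; args$use_cc <- TRUE
      args$Xu <- su$X; args$yu <- spec$yu; args$pop_mode <- 2L
      std$c <- sc
      par_names <- c(paste0("betaC_", colnames(spec$Xc)), "gamma0", "gamma1",
                     "p_branch1", paste0("betaT_", colnames(spec$Xt)))
      prior_mean <- c(rep(reg_m, ncol(sc$X)), priors$gamma0_mean,
                      priors$gamma1_mean, 0, rep(reg_m, ncol(st$X)))
      prior_sd <- c(rep(reg_s, ncol(sc$X)), priors$gamma0_sd,
                    priors$gamma1_sd, 1, rep(reg_s, ncol(st$X)))
      init <- c(rep(0, ncol(sc$X)), 0, 1,
                logit(priors$branch_alpha /
                        (priors$branch_alpha + priors$branch_beta)),
                rep(0, ncol(st$X)))
    }
  } else {
    stop("unknown model spec type: ", spec$type)
  }
  list(args = args, par_names = par_names, prior_mean = prior_mean,
       prior_sd = prior_sd, init = init, std = std, spec = spec)
}

# Laplace starting point: a GLM fit per block gives the posterior mode and
# curvature (the priors are vague), used to initialise chains and seed the
# adaptive proposal. Any block where the GLM fails (e.g. separation) falls
# back to a neutral start with a small isotropic proposal for that block.
safe_glm <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  co <- fit$coefficients
  if (any(!is.finite(co)) || any(abs(co) > 30)) return(NULL)
  XtWX <- crossprod(X * sqrt(fit$weights))
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) return(NULL)
  list(coef = unname(co), vcov = unname(V))
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  S <- matrix(0, sum(sizes), sum(sizes))
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    S[idx, idx] <- b
    at <- at + nrow(b)
  }
  S
}

laplace_start <- function(prep, priors) {
  spec <- prep$spec
  d <- length(prep$init)
  init <- prep$init
  blocks <- list()   # covariance blocks for the Metropolis coordinates
  ok <- TRUE
  fallback <- function(p) diag(0.05^2, p)
  p1_init <- function(m, n) {
    logit((priors$branch_alpha + m) /
            (priors$branch_alpha + priors$branch_beta + n))
  }

  if (spec$type == "logistic") {
    g <- safe_glm(prep$args$Xu, prep$args$yu)
    if (is.null(g)) { blocks <- list(fallback(d)); ok <- FALSE }
    else { init <- g$coef; blocks <- list(g$vcov) }
  } else if (spec$type == "beta_bernoulli") {
    init <- p1_init(spec$m, spec$n)
    return(list(init = init, chol = NULL))
  } else if (spec$type == "joint_recalibration") {
    pC <- ncol(spec$Xc)
    gc_ <- safe_glm(prep$args$Xc, prep$args$yc)
    if (is.null(gc_)) {
      blocks <- list(fallback(pC), fallback(2)); ok <- FALSE
    } else {
      z <- as.vector(prep$args$Xu %*% gc_$coef)
      gg <- safe_glm(cbind(1, z), prep$args$yu)
      if (is.null(gg)) {
        init <- c(gc_$coef, 0, 1)
        blocks <- list(gc_$vcov, fallback(2))
      } else {
        init <- c(gc_$coef, gg$coef)
        blocks <- list(gc_$vcov, gg$vcov)
      }
    }
  } else if (spec$type == "mixture") {
    gt <- safe_glm(prep$args$Xt, prep$args$yt)
    pT <- ncol(spec$Xt)
    tcoef <- if (is.null(gt)) rep(0, pT) else gt$coef
    tV <- if (is.null(gt)) fallback(pT) else gt$vcov
    if (spec$mode == "reestimation") {
      pU <- ncol(spec$Xu)
      gu <- safe_glm(prep$args$Xu, prep$args$yu)
      ucoef <- if (is.null(gu)) rep(0, pU) else gu$coef
      uV <- if (is.null(gu)) fallback(pU) else gu$vcov
      init <- c(ucoef, p1_init(spec$m1, spec$n1), tcoef)
      blocks <- list(uV, tV)
    } else {
      pC <- ncol(spec$Xc)
      gc_ <- safe_glm(prep$args$Xc, prep$args$yc)
      if (is.null(gc_)) {
        ccoef <- rep(0, pC); cV <- fallback(pC); gcoef <- c(0, 1)
        gV <- fallback(2)
      } else {
        ccoef <- gc_$coef; cV <- gc_$vcov
        z <- as.vector(prep$args$Xu %*% gc_$coef)
        gg <- safe_glm(cbind(1, z), prep$args$yu)
        gcoef <- if (is.null(gg)) c(0, 1) else gg$coef
        gV <- if (is.null(gg)) fallback(2) else gg$vcov
      }
      init <- c(ccoef, gcoef, p1_init(spec$m1, spec$n1), tcoef)
      blocks <- list(cV, gV, tV)
    }
  }
  S <- block_diag(blocks)
  dm <- nrow(S)
  ch <- tryCatch(t(chol(2.38^2 / dm * S)), error = function(e) NULL)
  list(init = init, chol = ch)
}

# back-transform one chain of standardized draws to the natural scale; the
# constrained branch logit is mapped to a probability
natural_scale_chain <- function(draws, prep) {
  spec <- prep$spec
  out <- draws
  if (spec$type == "logistic") {
    out <- destandardize_coefs(draws, prep$std$u$center, prep$std$u$scale)
  } else if (spec$type == "beta_bernoulli") {
    out[, 1] <- inv_logit(draws[, 1])
  } else if (spec$type == "joint_recalibration") {
    pC <- ncol(spec$Xc)
    out[, seq_len(pC)] <- destandardize_coefs(
      draws[, seq_len(pC), drop = FALSE],
      prep$std$c$center, prep$std$c$scale)
  } else if (spec$type == "mixture") {
    pT <- ncol(spec$Xt)
    if (spec$mode == "reestimation") {
      pU <- ncol(spec$Xu)
      out[, seq_len(pU)] <- destandardize_coefs(
        draws[, seq_len(pU), drop = FALSE],
        prep$std$u$center, prep$std$u$scale)
      out[, pU + 1] <- inv_logit(draws[, pU + 1])
      tcols <- pU + 1 + seq_len(pT)
    } else {
      pC <- ncol(spec$Xc)
      out[, seq_len(pC)] <- destandardize_coefs(
        draws[, seq_len(pC), drop = FALSE],
        prep$std$c$center, prep$std$c$scale)
      out[, pC + 3] <- inv_logit(draws[, pC + 3])
      tcols <- pC + 3 + seq_len(pT)
    }
    out[, tcols] <- destandardize_coefs(
      draws[, tcols, drop = FALSE],
      prep$std$t$center, prep$std$t$scale)
  }
  out
}

#' Draw from the posterior of a block-structured model
#'
#' Runs independent MCMC chains (adaptive random-walk Metropolis for
#' regression parameters, slice sampling for the constrained branch
#' probability) on the posterior described by a model specification, and
#' returns post-burn-in draws on the natural coefficient scale with split
#' R-hat diagnostics attached. Continuous covariates are centred and scaled
#' internally for sampler efficiency; reported coefficients are always on
#' the original scale. A convergence warning (never an error) is raised when
#' any R-hat exceeds the configured threshold.
#'
#' @param model_spec A specification built by one of the internal
#'   constructors (`spec_logistic()`, `spec_beta_bernoulli()`,
#'   `spec_joint_recalibration()`, `spec_mixture()`); the fitting functions
#'   build these for you.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_samples` object: a draws array (iteration, chain,
#'   parameter), per-parameter R-hat, and metadata.
#' @export
sample_posterior <- function(model_spec, priors = prior_spec(),
                             mcmc = mcmc_config()) {
  prep <- prepare_spec(model_spec, priors)
  d <- length(prep$init)
  n_keep <- (mcmc$n_iterations - mcmc$n_burnin) %/% mcmc$thin

  start <- laplace_start(prep, priors)
  prop_chol <- if (is.null(start$chol)) matrix(0, 0, 0) else start$chol
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(2147483646L, mcmc$n_chains)
  chains <- vector("list", mcmc$n_chains)
  acc <- numeric(mcmc$n_chains)
  for (k in seq_len(mcmc$n_chains)) {
    set.seed(chain_seeds[k])
    init <- start$init + stats::rnorm(d, 0, 0.1)
    res <- run_chain_cpp(prep$args$Xc, prep$args$yc, prep$args$use_cc,
                         prep$args$Xu, prep$args$yu, prep$args$pop_mode,
                         prep$args$use_b1, prep$args$m1, prep$args$n1,
                         prep$args$a1, prep$args$b1,
                         prep$args$Xt, prep$args$yt, prep$args$use_t,
                         prep$prior_mean, prep$prior_sd, init,
                         mcmc$n_iterations, mcmc$n_burnin, mcmc$thin,
                         2.0, prop_chol)
    chains[[k]] <- natural_scale_chain(res$draws, prep)
    acc[k] <- res$accept_rate
  }

  draws <- array(NA_real_, dim = c(n_keep, mcmc$n_chains, d),
                 dimnames = list(NULL, NULL, prep$par_names))
  for (k in seq_len(mcmc$n_chains)) draws[, k, ] <- chains[[k]]

  rh <- vapply(seq_len(d), function(j) as.numeric(rhat(draws[, , j])),
               numeric(1))
  names(rh) <- prep$par_names
  if (any(rh > mcmc$rhat_threshold)) {
    warning(sprintf("R-hat above %.3f for: %s", mcmc$rhat_threshold,
                    paste(prep$par_names[rh > mcmc$rhat_threshold],
                          collapse = ", ")),
            call. = FALSE)
  }
  structure(list(draws = draws, parameters = prep$par_names, rhat = rh,
                 accept_rate = acc,
                 metadata = list(model = model_spec$type,
                                 seed = mcmc$seed,
                                 n_chains = mcmc$n_chains,
                                 n_iterations = mcmc$n_iterations,
                                 n_burnin = mcmc$n_burnin,
                                 thin = mcmc$thin,
                                 fingerprint = spec_fingerprint(model_spec))),
            class = "posterior_samples")
}

spec_fingerprint <- function(spec) {
  nums <- unlist(lapply(spec, function(el) {
    if (is.numeric(el)) sum(el) else 0
  }))
  sprintf("%s:%.6g", spec$type, sum(nums))
}

#' @export
as.matrix.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(NA_real_, d[1] * d[2], d[3],
                dimnames = list(NULL, x$parameters))
  for (j in seq_len(d[3])) out[, j] <- as.vector(x$draws[, , j])
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_samples: %d parameters, %d chains x %d draws\n",
              d[3], d[2], d[1]))
  m <- as.matrix(x)
  summ <- data.frame(mean = colMeans(m),
                     sd = apply(m, 2, stats::sd),
                     `q2.5` = apply(m, 2, stats::quantile, 0.025),
                     `q97.5` = apply(m, 2, stats::quantile, 0.975),
                     rhat = x$rhat, check.names = FALSE)
  print(round(summ, 4))
  invisible(x)
}

#' Summarise posterior draws
#'
#' @param object A `posterior_samples` object.
#' @param ... Unused.
#' @return A data frame with posterior mean, sd, 95% interval and R-hat per
#'   parameter.
#' @export
summary.posterior_samples <- function(object, ...) {
  m <- as.matrix(object)
  data.frame(parameter = object$parameters,
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = apply(m, 2, stats::quantile, 0.025),
             q97.5 = apply(m, 2, stats::quantile, 0.975),
             rhat = object$rhat, row.names = NULL)
}

#' Write / read a posterior archive
#'
#' A posterior archive is a directory holding one plain-text array per
#' parameter (one column per chain, full `%.17g` precision so doubles
#' round-trip exactly) plus a JSON manifest with parameter names, R-hat
#' values and fit metadata.
#'
#' @param ps A `posterior_samples` object.
#' @param dir Directory to create/read.
#' @return `write_posterior()` returns `dir` invisibly; `read_posterior()`
#'   returns the reconstructed `posterior_samples`.
#' @export
write_posterior <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ps$draws)
  manifest <- list(parameters = ps$parameters, rhat = as.list(ps$rhat),
                   n_draws = d[1], n_chains = d[2],
                   accept_rate = ps$accept_rate, metadata = ps$metadata)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_len(d[3])) {
    m <- ps$draws[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = d[2])
    txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, file.path(dir, sprintf("param_%03d.csv", j)))
  }
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pn <- manifest$parameters
  d <- c(manifest$n_draws, manifest$n_chains, length(pn))
  draws <- array(NA_real_, dim = d, dimnames = list(NULL, NULL, pn))
  for (j in seq_along(pn)) {
    txt <- readLines(file.path(dir, sprintf("param_%03d.csv", j)))
    m <- do.call(rbind, lapply(strsplit(txt, ","), as.numeric))
    draws[, , j] <- m
  }
  structure(list(draws = draws, parameters = pn,
                 rhat = unlist(manifest$rhat),
                 accept_rate = manifest$accept_rate,
                 metadata = manifest$metadata),
            class = "posterior_samples")
}
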
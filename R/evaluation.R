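## Discrimination, calibration and bootstrap-stability assessment.

#' Area under the ROC curve
#'
#' Mann-Whitney probability of concordance: the probability that a random
#' case receives a higher predicted probability than a random control, with
#' ties counted one half. Invariant under strictly monotone transforms of
#' the predictions.
#'
#' @param probs Numeric predictions.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(probs, labels) {
  if (length(probs) != length(labels)) stop("length mismatch")
  if (any(is.na(probs)) || any(is.na(labels))) stop("missing values")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC with a posterior credible interval
#'
#' Computes the AUROC separately for every posterior draw of the predicted
#' probabilities and summarises the resulting distribution by its mean and
#' central 95% interval.
#'
#' @param prob_draws Draws-by-subjects matrix of predicted probabilities.
#' @param labels Binary labels (length = number of subjects).
#' @param max_draws Cap on the number of draws scored (evenly strided);
#'   ranking every draw of a long chain adds nothing at desk scale.
#' @return Named vector `mean`, `lo`, `hi`.
#' @export
auroc_credible <- function(prob_draws, labels, max_draws = 2000) {
  prob_draws <- as.matrix(prob_draws)
  if (ncol(prob_draws) != length(labels)) stop("dimension mismatch")
  nd <- nrow(prob_draws)
  if (nd > max_draws) {
    prob_draws <- prob_draws[round(seq(1, nd, length.out = max_draws)), ,
                             drop = FALSE]
  }
  a <- apply(prob_draws, 1, auroc, labels = labels)
  c(mean = mean(a),
    lo = unname(stats::quantile(a, 0.025)),
    hi = unname(stats::quantile(a, 0.975)))
}

#' Calibration curve by quantile bins
#'
#' Ranks subjects by predicted probability and cuts at rank boundaries
#' (quintiles by default; ties share the lower bin), then compares each
#' bin's mean prediction with its observed event proportion. With constant
#' predictions all subjects fall into a single effective bin, which is
#' flagged.
#'
#' @param probs Predicted probabilities (point estimates).
#' @param labels Binary labels.
#' @param n_bins Number of quantile bins (default 5).
#' @return A `calibration_curve`: per-bin mean prediction, observed
#'   proportion and count.
#' @export
calibration_curve <- function(probs, labels, n_bins = 5) {
  n <- length(probs)
  if (n < n_bins) stop("need at least n_bins observations")
  if (length(labels) != n) stop("length mismatch")
  ord <- order(probs)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  # ties share the lower bin
  if (anyDuplicated(probs)) bin <- as.integer(stats::ave(bin, probs, FUN = min))
  bins <- sort(unique(bin))
  df <- data.frame(
    bin = bins,
    n = vapply(bins, function(b) sum(bin == b), integer(1)),
    mean_predicted = vapply(bins, function(b) mean(probs[bin == b]),
                            numeric(1)),
    observed = vapply(bins, function(b) mean(labels[bin == b]), numeric(1)))
  structure(list(bins = df, n_bins_requested = n_bins,
                 degenerate = length(bins) < n_bins),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %d effective bins (%d requested)%s\n",
              nrow(x$bins), x$n_bins_requested,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$bins)
  invisible(x)
}

#' Calibration-in-the-large error
#'
#' Difference between mean predicted probability and the observed event
#' rate; zero for a model calibrated in the large.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @return Signed numeric error.
#' @export
calibration_in_the_large <- function(probs, labels) {
  mean(probs) - mean(labels)
}

#' Bootstrap stability analysis
#'
#' Refits a model on nonparametric bootstrap resamples of the cohort
#' (subjects drawn with replacement, size fixed) and evaluates every refit
#' on the original subjects. The spread of replicate predictions around the
#' original model's predictions measures how stable individual risk
#' estimates are under sampling noise. Replicates containing fewer than 3
#' cases are retained but flagged.
#'
#' @param pop A `subject_dataset` (or any data frame the callback accepts).
#' @param fit_and_predict Function `(train_data, newdata) ->` numeric vector
#'   of per-subject predicted probabilities.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed for resampling.
#' @return A `stability_result`: original predictions, an n-by-B replicate
#'   prediction matrix, and low-case flags.
#' @export
stability_bootstrap <- function(pop, fit_and_predict, B = 100, seed = 1L) {
  if (B < 2) stop("B must be >= 2")
  n <- nrow(pop)
  original <- fit_and_predict(pop, pop)
  reps <- matrix(NA_real_, n, B)
  low_cases <- logical(B)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    boot <- pop[idx, ]
    low_cases[b] <- sum(boot$disease_label == 1, na.rm = TRUE) < 3
    reps[, b] <- fit_and_predict(boot, pop)
  }
  structure(list(original = original, replicates = reps, B = B,
                 low_case_flag = low_cases),
            class = "stability_result")
}

#' Pointwise stability envelopes
#'
#' Central quantile envelopes of the replicate predictions for each
#' subject, plus their mean width, for comparing the stability of
#' competing model-building procedures.
#'
#' @param sr A `stability_result`.
#' @param level Envelope coverage (default 0.95; the 50% envelope is also
#'   standard).
#' @return Data frame with per-subject original prediction, envelope
#'   bounds and width; mean width as attribute `mean_width`.
#' @export
stability_envelope <- function(sr, level = 0.95) {
  stopifnot(inherits(sr, "stability_result"))
  a <- (1 - level) / 2
  lo <- apply(sr$replicates, 1, stats::quantile, a)
  hi <- apply(sr$replicates, 1, stats::quantile, 1 - a)
  out <- data.frame(original = sr$original, lo = lo, hi = hi,
                    width = hi - lo)
  attr(out, "mean_width") <- mean(out$width)
  out
}
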
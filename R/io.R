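## Dataset I/O and the end-to-end pipeline.

#' Write / read subject-level datasets as CSV
#'
#' One row per subject with the documented header (sex, parent_affected,
#' age_at_diagnosis, age_at_recruitment, bmi, hba1c, cpep_status,
#' antibody_status, t_indicator, disease_label); missing values are empty
#' fields. `write_dataset()` also writes a JSON provenance sidecar
#' (`<path>.provenance.json`) recording the design and how the data arose.
#' `read_dataset()` validates the header exactly, re-applies every dataset
#' invariant (failures name the offending rows) and logs a row-count and
#' missingness summary.
#'
#' @param dataset A `subject_dataset`.
#' @param path CSV file path.
#' @param design Design of the dataset being read ("population" or
#'   "case_control"); defaults to the sidecar's record when present.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `subject_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "subject_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "")
  jsonlite::write_json(list(design = attr(dataset, "design"),
                            provenance = attr(dataset, "provenance"),
                            n = nrow(dataset)),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, design = NULL) {
  sidecar <- paste0(path, ".provenance.json")
  provenance <- paste("read from", path)
  if (is.null(design) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    design <- meta$design
    provenance <- meta$provenance
  }
  if (is.null(design)) design <- "population"
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        colClasses = c(sex = "integer",
                                       parent_affected = "integer",
                                       age_at_diagnosis = "numeric",
                                       age_at_recruitment = "numeric",
                                       bmi = "numeric", hba1c = "numeric",
                                       cpep_status = "character",
                                       antibody_status = "character",
                                       t_indicator = "integer",
                                       disease_label = "integer"))
  unknown <- setdiff(names(df), DATASET_COLUMNS)
  if (length(unknown)) {
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  }
  out <- new_dataset(df, design = design, provenance = provenance)
  message(sprintf("read %d records (%d labeled, %d cases) from %s",
                  nrow(out), sum(!is.na(out$disease_label)),
                  sum(out$disease_label == 1, na.rm = TRUE), path))
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles and validates everything one pipeline run needs: the method, the
#' scenario it is valid under (mixture methods require scenario "c", which
#' keeps all subjects and their biomarker composition; the others use "a"
#' or "b"), dataset paths or generator settings, prior/MCMC overrides, an
#' output directory and a seed. The prevalence used by the conversion-table
#' and offset methods defaults to the empirical labeled prevalence of the
#' population dataset under the active scenario and can be overridden.
#'
#' @param method One of "original", "albert_offset", "reestimation",
#'   "recalibration", "reestimation_mixture", "recalibration_mixture".
#' @param scenario "a", "b" or "c".
#' @param output_dir Directory for artifacts.
#' @param seed Integer seed governing every random stage.
#' @param generator Named overrides passed to [generator_config()]; used
#'   when dataset paths are not given.
#' @param generate_data When `FALSE`, no synthetic data is generated and
#'   dataset paths must be supplied.
#' @param cc_path,pop_path Optional CSV paths for existing datasets.
#' @param prevalence Optional prevalence override for the original/offset
#'   methods.
#' @param mcmc Named overrides passed to [mcmc_config()].
#' @return A validated `run_config`.
#' @export
run_config <- function(method, scenario, output_dir, seed = 1L,
                       generator = list(), generate_data = TRUE,
                       cc_path = NULL, pop_path = NULL,
                       prevalence = NULL, mcmc = list()) {
  methods <- c("original", "albert_offset", "reestimation", "recalibration",
               "reestimation_mixture", "recalibration_mixture")
  method <- match.arg(method, methods)
  scenario <- match.arg(scenario, c("a", "b", "c"))
  is_mixture <- grepl("mixture", method)
  if (is_mixture && scenario != "c") {
    stop("mixture methods require scenario c")
  }
  if (!is_mixture && scenario == "c") {
    stop("scenario c is reserved for mixture methods")
  }
  if (!generate_data && is.null(cc_path) &&
      method != "reestimation" && method != "reestimation_mixture") {
    stop("without synthetic generation, cc_path is required for this method")
  }
  if (method %in% c("original", "albert_offset") &&
      is.null(prevalence) && is.null(pop_path) && !generate_data) {
    stop("original/albert_offset need a prevalence estimate or a population dataset to derive one")
  }
  structure(list(method = method, scenario = scenario,
                 output_dir = output_dir, seed = as.integer(seed),
                 generator = generator, generate_data = generate_data,
                 cc_path = cc_path, pop_path = pop_path,
                 prevalence = prevalence, mcmc = mcmc),
            class = "run_config")
}

scenario_validation_set <- function(pop, scenario) {
  if (scenario == "a") {
    val <- pop
    val$disease_label[is.na(val$disease_label)] <- 0L
    val
  } else {
    val <- pop[pop$t_indicator == 0, ]
    val
  }
}

#' Run the full generation / fitting / evaluation pipeline
#'
#' Generates (or loads) the case-control and population datasets, fits the
#' configured method, predicts on the scenario's validation population
#' (scenario "a": all subjects with unobserved labels treated as negative;
#' scenarios "b"/"c": the biomarker-screened subset), evaluates
#' discrimination and calibration, and writes every artifact plus a
#' manifest to the output directory. Reproducible: the manifest and all
#' tables are a deterministic function of the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fit, predictions, evaluation summary
#'   and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  gen <- do.call(generator_config, c(config$generator,
                                     list(seed = config$seed)))
  if (!config$generate_data &&
      (is.null(config$pop_path) || is.null(config$cc_path))) {
    stop("generate_data = FALSE requires dataset paths")
  }
  cc <- if (!is.null(config$cc_path)) {
    read_dataset(config$cc_path, "case_control")
  } else generate_case_control(gen)
  pop <- if (!is.null(config$pop_path)) {
    read_dataset(config$pop_path, "population")
  } else apply_testing_cascade(generate_population(gen))

  mcmc <- do.call(mcmc_config, c(config$mcmc, list(seed = config$seed)))
  priors <- prior_spec()
  scen_ab <- if (config$scenario == "c") "b" else config$scenario
  val <- scenario_validation_set(pop, scen_ab)
  labels <- val$disease_label

  prevalence <- config$prevalence
  if (is.null(prevalence)) {
    scen_pop <- scenario_validation_set(pop, scen_ab)
    prevalence <- mean(scen_pop$disease_label)
    message(sprintf("using empirical scenario-%s prevalence %.4f",
                    config$scenario, prevalence))
  }

  method <- config$method
  fit <- NULL
  extra <- list()
  if (method == "original") {
    fit <- fit_training_model(cc, priors, mcmc)
    cc_probs <- colMeans(predict_training(fit, cc))
    tab <- build_conversion_table(cc_probs, cc$disease_label,
                                  target_prevalence = prevalence)
    point <- apply_conversion(tab, colMeans(predict_training(fit, val)))
    pred <- matrix(point, nrow = 1)
    extra$conversion_table <- tab
    write_conversion_table(tab, file.path(config$output_dir,
                                          "conversion_table.csv"))
  } else if (method == "albert_offset") {
    fit <- fit_training_model(cc, priors, mcmc)
    pred <- albert_offset_predict(fit, val,
                                  odds_target = prob_to_odds(prevalence))
  } else if (method == "reestimation") {
    fit <- fit_reestimation(pop, priors, mcmc, scenario = config$scenario)
    pred <- predict(fit, val)
  } else if (method == "recalibration") {
    fit <- fit_joint_recalibration(cc, pop, priors, mcmc,
                                   scenario = config$scenario)
    pred <- predict(fit, val)
  } else {
    mode <- if (method == "reestimation_mixture") "reestimation" else
      "recalibration"
    fit <- fit_mixture(pop, mode = mode,
                       cc = if (mode == "recalibration") cc else NULL,
                       priors = priors, mcmc = mcmc)
    pred <- predict_mixture(fit, val, biomarker_status = "T0")
  }

  point <- colMeans(pred)
  evaluation <- list(
    method = method, scenario = config$scenario,
    n_validation = nrow(val), prevalence_used = prevalence,
    auroc = auroc(point, labels),
    calibration_in_the_large = calibration_in_the_large(point, labels))
  if (nrow(pred) > 1) {
    ac <- auroc_credible(pred, labels)
    evaluation$auroc_mean <- ac[["mean"]]
    evaluation$auroc_lo <- ac[["lo"]]
    evaluation$auroc_hi <- ac[["hi"]]
  }
  cal <- calibration_curve(point, labels)
  evaluation$calibration_bins <- cal$bins
  if (!is.null(fit$posterior)) {
    evaluation$max_rhat <- max(fit$posterior$rhat)
    write_posterior(fit$posterior, file.path(config$output_dir, "posterior"))
  }

  pred_df <- data.frame(prob_mean = point,
                        prob_lo = apply(pred, 2, stats::quantile, 0.025),
                        prob_hi = apply(pred, 2, stats::quantile, 0.975),
                        label = labels)
  utils::write.csv(pred_df, file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(evaluation,
                       file.path(config$output_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    package_version = as.character(utils::packageVersion("raremix")),
    method = method, scenario = config$scenario, seed = config$seed,
    prevalence = prevalence, generator = config$generator,
    mcmc = config$mcmc,
    datasets = list(cc = attr(cc, "provenance"),
                    pop = attr(pop, "provenance")))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, predictions = pred_df, evaluation = evaluation,
                 extra = extra, output_dir = config$output_dir))
}
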
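#' Pipeline configuration
#'
#' Orchestration config for [run_pipeline()]: exactly one of `input_path`
#' (a trial CSV) or `sim` (a [sim_config()] for a synthetic trial) must be
#' given.
#'
#' @param input_path Path to a trial CSV, or `NULL`.
#' @param sim A [sim_config()] (or argument list for one), or `NULL`.
#' @param output_dir Directory for artifacts (created if absent).
#' @param sampler A [sampler_config()].
#' @param prior_sd_beta,prior_sd_scales Prior SDs for all models.
#' @param thresholds Named list of threshold vectors per outcome
#'   (defaults: [default_thresholds()]).
#' @param seed Master seed: resets the sampler seed and, in simulate mode,
#'   the generator seed, so the manifest alone reproduces every artifact.
#' @param allow_warnings If `FALSE`, a convergence flag makes
#'   [run_pipeline()] return status 1.
#' @param verbosity 0 silent, 1 stage messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, sim = NULL,
                            output_dir = "auditbi-run",
                            sampler = sampler_config(),
                            prior_sd_beta = 1, prior_sd_scales = 1,
                            thresholds = NULL, seed = 1L,
                            allow_warnings = TRUE, verbosity = 1L) {
  if (is.null(input_path) == is.null(sim))
    stop("exactly one of `input_path` and `sim` must be given", call. = FALSE)
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  thresholds <- utils::modifyList(
    list(risk = default_thresholds("risk"),
         audit_total = default_thresholds("audit_total"),
         audit_c = default_thresholds("audit_c")),
    thresholds %||% list())
  sampler$seed <- as.integer(seed)
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(input_path = input_path, sim = sim,
                 output_dir = output_dir, sampler = sampler,
                 prior_sd_beta = prior_sd_beta,
                 prior_sd_scales = prior_sd_scales,
                 thresholds = thresholds, seed = as.integer(seed),
                 allow_warnings = allow_warnings,
                 verbosity = verbosity),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `sim` and `sampler` are
#' nested key-value blocks.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (CLI flags take precedence
#'   over file values).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sampler)) vals$sampler <- do.call(sampler_config, vals$sampler)
  if (!is.null(vals$sim)) vals$sim <- do.call(sim_config, vals$sim)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain data (simulate or read) -> encode -> fit the three
#' hierarchical models (risk, AUDIT total, AUDIT-C) by HMC -> summarize at
#' the configured effect thresholds -> ML mixed-effects comparison ->
#' report. Artifacts written under `output_dir`: the trial CSV (simulate
#' mode), a design summary, per-model draws and diagnostics CSVs, density
#' figures and binned-density CSVs, the cumulative-probability tables, the
#' markdown report with frequentist panel, and a `manifest.json` recording
#' seed, configuration and versions.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0, or 1 if a convergence flag
#'   was raised and `allow_warnings` is `FALSE`), artifact `paths`, the
#'   fitted objects and summary tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbosity > 0) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  paths <- list()

  if (!is.null(config$sim)) {
    say("stage simulate: generating synthetic trial (seed %d)", config$seed)
    trial <- tryCatch(simulate_trial(config$sim), error = function(e)
      stop("stage simulate failed: ", conditionMessage(e), call. = FALSE))
    paths$trial_csv <- out("trial.csv")
    write_trial_csv(trial, paths$trial_csv)
    tab <- validate_trial_table(trial$table)
  } else {
    say("stage read: %s", config$input_path)
    tab <- tryCatch(read_trial_csv(config$input_path), error = function(e)
      stop("stage read failed: ", conditionMessage(e), call. = FALSE))
  }

  outcomes <- c("risk", "audit_total", "audit_c")
  fits <- list(); tables <- list(); diags <- list()
  for (oc in outcomes) {
    say("stage fit: %s model (%d chains x %d iterations)", oc,
        config$sampler$n_chains, config$sampler$n_iter)
    fits[[oc]] <- tryCatch(
      bi_fit(tab, oc, prior_sd_beta = config$prior_sd_beta,
             prior_sd_scales = config$prior_sd_scales,
             sampler = config$sampler),
      error = function(e) stop(sprintf("stage fit (%s) failed: %s", oc,
                                       conditionMessage(e)), call. = FALSE))
    paths[[paste0("draws_", oc)]] <- out(sprintf("draws_%s.csv", oc))
    write_draws_csv(fits[[oc]]$draws, paths[[paste0("draws_", oc)]])
    diags[[oc]] <- fits[[oc]]$diagnostics
    utils::write.table(diags[[oc]]$table, out(sprintf("diagnostics_%s.csv", oc)),
                       sep = ",", quote = FALSE, row.names = FALSE)
    tables[[oc]] <- effect_table(fits[[oc]], config$thresholds[[oc]])
    utils::write.table(as.data.frame(tables[[oc]]),
                       out(sprintf("effect_table_%s.csv", oc)),
                       sep = ",", quote = FALSE, row.names = FALSE)
    paths[[paste0("density_", oc)]] <- out(sprintf("density_%s.png", oc))
    density_export(effect_samples(fits[[oc]]$draws),
                   paths[[paste0("density_", oc)]],
                   ref_value = if (oc == "risk") 1 else 0,
                   xlab = if (oc == "risk") "odds ratio"
                          else "mean difference (points)")
  }

  say("stage compare: ML mixed-effects logistic fit")
  freq <- tryCatch(fit_ml_mixed_logistic(fits$risk$design),
                   error = function(e) stop("stage compare failed: ",
                                            conditionMessage(e), call. = FALSE))
  paths$comparison <- out("comparison.md")
  compare_frequentist(freq, tables$risk, paths$comparison)
  utils::write.table(
    data.frame(parameter = names(freq$beta_hat), estimate = freq$beta_hat,
               se = freq$se, row.names = NULL),
    out("frequentist_coefficients.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)

  say("stage report")
  design <- fits$risk$design
  writeLines(sprintf(
    "outcome,n_completers,k_centers,n_columns\n%s,%d,%d,%d",
    "risk", design$n, design$k, ncol(design$X)), out("design_summary.csv"))
  paths$report <- out("report.md")
  effect_report(tables, diagnostics = diags, freq = freq, path = paths$report)

  manifest <- list(
    package = "auditbi",
    version = as.character(utils::packageVersion("auditbi")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    mode = if (is.null(config$sim)) "input" else "simulate",
    input_path = config$input_path,
    sim = if (!is.null(config$sim)) unclass(config$sim),
    sampler = unclass(config$sampler),
    priors = list(prior_sd_beta = config$prior_sd_beta,
                  prior_sd_scales = config$prior_sd_scales),
    thresholds = config$thresholds
  )
  paths$manifest <- out("manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  flagged <- unlist(lapply(diags, `[[`, "flagged"))
  status <- if (length(flagged) && !config$allow_warnings) 1L else 0L
  if (status == 1L)
    warning("convergence flags raised: ", paste(flagged, collapse = ", "))
  invisible(list(status = status, paths = paths, fits = fits,
                 tables = tables, freq = freq, diagnostics = diags))
}
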
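#' Fit a Bayesian hierarchical outcome model to a trial table
#'
#' The main entry point: takes a per-participant trial table (or a CSV
#' path, or a [simulate_trial()] result), restricts to completers, encodes
#' the design, builds the hierarchical Bernoulli-logit (`outcome = "risk"`)
#' or Gaussian (score outcomes, baseline-adjusted) model with health-center
#' random intercepts and weakly-informative normal priors centered on the
#' null, and samples the posterior by Hamiltonian Monte Carlo.
#'
#' @param data A trial table data frame, a `synthetic_trial`, or a path to
#'   a trial CSV.
#' @param outcome `"risk"` (binary risky drinking at follow-up, AUDIT
#'   total >= 8), `"audit_total"` or `"audit_c"` (follow-up scores,
#'   baseline-adjusted).
#' @param prior_sd_beta,prior_sd_scales Prior SDs (defaults 1; see
#'   [hb_model()]).
#' @param sampler A [sampler_config()].
#' @param ... Passed to [encode_design()] (e.g. `sex_reference`,
#'   `standardize_age`) or [hb_model()] (`parameterization`).
#' @return An object of class `bi_fit` wrapping the model, design, draws
#'   and diagnostics, with `print`, `summary`, `coef`, `plot` and
#'   `as.data.frame` methods.
#' @examples
#' \donttest{
#' trial <- simulate_trial(sim_config(seed = 7))
#' fit <- bi_fit(trial, "risk", sampler = sampler_config(preset = "test"))
#' fit
#' summary(fit)
#' effect_table(fit)
#' }
#' @export
bi_fit <- function(data, outcome = c("risk", "audit_total", "audit_c"),
                   prior_sd_beta = 1, prior_sd_scales = 1,
                   sampler = sampler_config(), ...) {
  outcome <- match.arg(outcome)
  cl <- match.call()
  if (is.character(data) && length(data) == 1) data <- read_trial_csv(data)
  dots <- list(...)
  enc_args <- dots[intersect(names(dots),
                             c("sex_reference", "standardize_age"))]
  mod_args <- dots[intersect(names(dots), "parameterization")]
  design <- do.call(encode_design, c(list(data, outcome = outcome), enc_args))
  model <- do.call(hb_model,
                   c(list(design, prior_sd_beta = prior_sd_beta,
                          prior_sd_scales = prior_sd_scales), mod_args))
  draws <- hmc_sample(model, sampler)
  structure(list(call = cl, outcome = outcome, design = design,
                 model = model, draws = draws,
                 diagnostics = if (draws$n_chains >= 2)
                   mcmc_diagnostics(draws) else NULL),
            class = "bi_fit")
}

#' @export
print.bi_fit <- function(x, ...) {
  eff <- effect_samples(x$draws)
  cat(sprintf("Bayesian hierarchical %s model (%s outcome)\n",
              x$model$kind, x$outcome))
  cat(sprintf("  n = %d completers, k = %d centers; %d chains x %d draws\n",
              x$design$n, x$design$k, x$draws$n_chains, x$draws$n_iter))
  if (x$outcome == "risk") {
    cat(sprintf("  posterior mean OR %.3f; P(OR < 1) = %.3f\n",
                mean(eff), mean(eff < 1)))
  } else {
    cat(sprintf("  posterior mean reduction %.3f points; P(any reduction) = %.3f\n",
                -mean(eff), mean(eff < 0)))
  }
  if (!is.null(x$diagnostics) && length(x$diagnostics$flagged))
    cat("  WARNING: R-hat > 1.01 for",
        paste(x$diagnostics$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.bi_fit <- function(object, ...) {
  colMeans(object$draws$draws[, seq_len(object$model$p), drop = FALSE])
}

#' @rdname bi_fit
#' @param object,x A `bi_fit` object.
#' @export
summary.bi_fit <- function(object, ...) {
  d <- object$draws$draws
  tab <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q50 = apply(d, 2, stats::quantile, 0.5),
    q97.5 = apply(d, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  if (!is.null(object$diagnostics)) {
    tab$rhat <- object$diagnostics$table$rhat
    tab$ess_bulk <- object$diagnostics$table$ess_bulk
  }
  structure(list(outcome = object$outcome, n = object$design$n,
                 k = object$design$k, table = tab,
                 divergences = object$draws$divergences),
            class = "summary.bi_fit")
}

#' @export
print.summary.bi_fit <- function(x, ...) {
  cat(sprintf("Posterior summary: %s outcome, n = %d, k = %d centers\n",
              x$outcome, x$n, x$k))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("post-warmup divergences: %d\n", x$divergences))
  invisible(x)
}

#' @export
as.data.frame.bi_fit <- function(x, ...) {
  data.frame(chain = x$draws$chain_id, x$draws$draws, check.names = FALSE)
}

#' @export
plot.bi_fit <- function(x, ...) {
  eff <- effect_samples(x$draws)
  ref <- if (x$outcome == "risk") 1 else 0
  xlab <- if (x$outcome == "risk") "odds ratio (BI vs control)"
          else "mean difference (BI - control, points)"
  graphics::hist(eff, breaks = "FD", freq = FALSE, col = "grey85",
                 border = "grey55", xlab = xlab,
                 main = sprintf("Posterior of the intervention effect (%s)",
                                x$outcome), ...)
  graphics::lines(stats::density(eff), lwd = 2)
  graphics::abline(v = ref, lty = 2, lwd = 2, col = "firebrick")
  invisible(x)
}

#' Cumulative effect-probability table for a fitted model
#'
#' Convenience wrapper applying [cumulative_table()] to a [bi_fit()] with
#' the outcome's default thresholds and orientation.
#'
#' @param fit A `bi_fit` object.
#' @param thresholds Effect-size thresholds (defaults per outcome, see
#'   [default_thresholds()]).
#' @return An `effect_summary`.
#' @export
effect_table <- function(fit, thresholds = NULL) {
  stopifnot(inherits(fit, "bi_fit"))
  thresholds <- thresholds %||% default_thresholds(fit$outcome)
  cumulative_table(effect_samples(fit$draws), thresholds,
                   orientation = if (fit$outcome == "risk") "less_than"
                                 else "reduction_at_least",
                   outcome = fit$outcome)
}
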
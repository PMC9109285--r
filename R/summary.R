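# Decision-oriented posterior summaries: odds-ratio draws, cumulative
# effect-size probability tables, density exports, and the combined report.

#' Default effect-size thresholds per outcome
#'
#' Odds-ratio thresholds \{1, 0.8, 0.6\} for the risky-drinking outcome and
#' score-reduction thresholds \{0, 0.5, 1\} (AUDIT total) and
#' \{0, 0.25, 0.5\} (AUDIT-C) points.
#'
#' @param outcome `"risk"`, `"audit_total"` or `"audit_c"`.
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function(outcome = c("risk", "audit_total", "audit_c")) {
  switch(match.arg(outcome),
         risk = c(1, 0.8, 0.6),
         audit_total = c(0, 0.5, 1),
         audit_c = c(0, 0.25, 0.5))
}

#' Odds-ratio draws for the intervention effect
#'
#' Element-wise `exp` of the group-coefficient draws of the Bernoulli-logit
#' model: the posterior of the odds ratio of risky drinking at follow-up,
#' brief intervention versus control.
#'
#' @param draws A `posterior_draws` object from the Bernoulli-logit model.
#' @return Numeric vector of OR draws (chain labels kept as attribute).
#' @export
or_samples <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$model_kind != "bernoulli_logit")
    stop("or_samples() applies to the Bernoulli-logit (risk) model only",
         call. = FALSE)
  if (!"group" %in% colnames(draws$draws))
    stop("no `group` coefficient in draws", call. = FALSE)
  structure(exp(draws$draws[, "group"]), chain_id = draws$chain_id)
}

#' Intervention-effect draws on the reporting scale
#'
#' For the risk outcome, odds-ratio draws ([or_samples()]); for score
#' outcomes, the group-coefficient draws (follow-up mean difference,
#' intervention minus control, in score points).
#'
#' @param draws A `posterior_draws` object.
#' @return Numeric vector with a `chain_id` attribute.
#' @export
effect_samples <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$model_kind == "bernoulli_logit") return(or_samples(draws))
  structure(draws$draws[, "group"], chain_id = draws$chain_id)
}

#' Cumulative effect-size probability table
#'
#' The decision-oriented summary: for each threshold, the posterior
#' probability that the intervention effect is at least that favorable.
#' With `orientation = "less_than"` (odds ratios) the probability is
#' `P(effect < t)`. With `orientation = "reduction_at_least"` the samples
#' are mean differences coded intervention-minus-control and the
#' probability is `P(reduction >= t) = P(effect <= -t)`; reductions are
#' reported as positive magnitudes.
#'
#' Each probability carries a Monte-Carlo standard error from an
#' ESS-adjusted binomial variance.
#'
#' @param effect_samples Numeric vector of posterior effect draws.
#' @param thresholds Finite numeric thresholds.
#' @param orientation `"less_than"` or `"reduction_at_least"`.
#' @param outcome Optional outcome label stored in the table.
#' @return An object of class `effect_summary`: thresholds, cumulative
#'   probabilities, MC standard errors, posterior mean and central 95\%
#'   credible interval on the reporting scale.
#' @export
cumulative_table <- function(effect_samples,
                             thresholds,
                             orientation = c("less_than",
                                             "reduction_at_least"),
                             outcome = NULL) {
  orientation <- match.arg(orientation)
  x <- as.numeric(effect_samples)
  if (length(x) == 0) stop("empty effect samples", call. = FALSE)
  if (any(is.infinite(thresholds) & orientation == "reduction_at_least"))
    stop("thresholds must be finite", call. = FALSE)

  ind <- function(t) if (orientation == "less_than") x < t else x <= -t
  cum_prob <- vapply(thresholds, function(t) mean(ind(t)), 0)
  mc_se <- vapply(thresholds, function(t) {
    p <- mean(ind(t))
    ess <- ess_single(as.numeric(ind(t)))
    if (!is.finite(ess)) return(0)
    sqrt(p * (1 - p) / ess)
  }, 0)

  rep_scale <- if (orientation == "reduction_at_least") -x else x
  structure(list(
    outcome = outcome,
    orientation = orientation,
    thresholds = thresholds,
    cum_prob = cum_prob,
    mc_se = mc_se,
    posterior_mean = mean(rep_scale),
    ci95 = unname(stats::quantile(rep_scale, c(0.025, 0.975))),
    n_samples = length(x)
  ), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  lab <- if (x$orientation == "less_than") "P(effect < %g)"
         else "P(reduction >= %g)"
  cat(sprintf("Effect summary%s (%d draws)\n",
              if (is.null(x$outcome)) "" else paste0(": ", x$outcome),
              x$n_samples))
  for (j in seq_along(x$thresholds))
    cat(sprintf("  %-22s %.3f (MC-SE %.4f)\n",
                sprintf(lab, x$thresholds[j]), x$cum_prob[j], x$mc_se[j]))
  cat(sprintf("  posterior mean %.3f, 95%% CrI [%.3f, %.3f]\n",
              x$posterior_mean, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
as.data.frame.effect_summary <- function(x, ...) {
  data.frame(outcome = x$outcome %||% NA_character_,
             orientation = x$orientation,
             threshold = x$thresholds,
             cum_prob = x$cum_prob,
             mc_se = x$mc_se,
             posterior_mean = x$posterior_mean,
             ci95_lower = x$ci95[1],
             ci95_upper = x$ci95[2])
}

#' Export a posterior density (figure + binned CSV)
#'
#' Writes a histogram-density figure (with an optional reference line at
#' the null value) and a CSV of the binned density. Bins follow the
#' Freedman-Diaconis rule; a degenerate all-equal sample gets a single
#' unit-width bin.
#'
#' @param effect_samples Numeric vector (at least 100 draws).
#' @param path Figure path; the device is chosen by extension
#'   (`.png`, `.pdf`, `.svg`). The binned CSV is written alongside with a
#'   `.csv` extension unless `csv_path` is given.
#' @param csv_path Optional CSV path.
#' @param ref_value Optional reference value drawn as a vertical line.
#' @param xlab X-axis label.
#' @return Invisible list with the figure and CSV paths and the bin table.
#' @export
density_export <- function(effect_samples, path, csv_path = NULL,
                           ref_value = NULL, xlab = "effect size") {
  x <- as.numeric(effect_samples)
  if (length(x) < 100)
    stop("need at least 100 samples for a density export", call. = FALSE)
  if (is.null(csv_path)) csv_path <- sub("\\.[A-Za-z]+$", ".csv", path)

  if (length(unique(x)) == 1) {
    breaks <- c(x[1] - 0.5, x[1] + 0.5)
  } else {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)   # Freedman-Diaconis
    if (bw <= 0) bw <- diff(range(x)) / 30
    breaks <- seq(min(x), max(x) + bw, by = bw)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  bins <- data.frame(bin_left = utils::head(h$breaks, -1),
                     bin_right = utils::tail(h$breaks, -1),
                     midpoint = h$mids, count = h$counts,
                     density = h$density)
  utils::write.table(bins, csv_path, sep = ",", quote = FALSE,
                     row.names = FALSE)

  ext <- tolower(sub(".*\\.", "", path))
  ok <- tryCatch({
    switch(ext,
           png = grDevices::png(path, width = 900, height = 600, res = 120),
           svg = grDevices::svg(path, width = 7.5, height = 5),
           grDevices::pdf(path, width = 7.5, height = 5))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(h, freq = FALSE, col = "grey85", border = "grey55",
                   main = "Posterior distribution", xlab = xlab)
    if (length(unique(x)) > 1)
      graphics::lines(stats::density(x), lwd = 2)
    if (!is.null(ref_value))
      graphics::abline(v = ref_value, lty = 2, lwd = 2, col = "firebrick")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write density figure: ", conditionMessage(ok),
         call. = FALSE)
  invisible(list(figure = path, csv = csv_path, bins = bins))
}

#' Combined effect-probability report
#'
#' Renders the cumulative-probability tables of the primary (risk odds
#' ratio) and secondary (AUDIT score reduction) outcomes as one markdown
#' document, with a diagnostics appendix; a warning section appears only
#' when a parameter is flagged for convergence.
#'
#' @param tables List of `effect_summary` objects.
#' @param diagnostics Optional list of [mcmc_diagnostics()] objects (named
#'   by outcome).
#' @param freq Optional `freq_fit` comparison ([fit_ml_mixed_logistic()]).
#' @param path Optional file to write the markdown to.
#' @return The markdown document as a character vector (invisibly if
#'   `path` is given).
#' @export
effect_report <- function(tables, diagnostics = NULL, freq = NULL,
                          path = NULL) {
  stopifnot(length(tables) > 0)
  lines <- c("# Posterior probabilities of intervention effects", "")
  for (tab in tables) {
    stopifnot(inherits(tab, "effect_summary"))
    title <- switch(tab$outcome %||% "effect",
                    risk = "Risky drinking (odds ratio)",
                    audit_total = "AUDIT total score (reduction, points)",
                    audit_c = "AUDIT-C score (reduction, points)",
                    tab$outcome %||% "Effect")
    lines <- c(lines, paste("##", title), "",
               "| Effect size | Posterior probability | MC-SE |",
               "|---|---|---|")
    for (j in seq_along(tab$thresholds)) {
      lab <- if (tab$orientation == "less_than")
        sprintf("Odds-ratio < %g", tab$thresholds[j])
      else if (tab$thresholds[j] == 0) "Any reduction"
      else sprintf("At least %g points", tab$thresholds[j])
      lines <- c(lines, sprintf("| %s | %.2f | %.4f |",
                                lab, tab$cum_prob[j], tab$mc_se[j]))
    }
    lines <- c(lines, "",
               sprintf("Posterior mean %.2f, 95%% CrI [%.2f, %.2f] (%d draws).",
                       tab$posterior_mean, tab$ci95[1], tab$ci95[2],
                       tab$n_samples), "")
  }

  if (!is.null(freq)) {
    lines <- c(lines, "## Frequentist comparison", "",
               sprintf("ML mixed-effects logistic regression: OR %.2f (95%% CI %.2f-%.2f), p = %.3f.",
                       freq$or_point, freq$or_ci95[1], freq$or_ci95[2],
                       freq$p_value), "")
  }

  if (!is.null(diagnostics)) {
    flagged <- unlist(lapply(diagnostics, `[[`, "flagged"))
    if (length(flagged))
      lines <- c(lines, "## WARNING: convergence flags", "",
                 paste("R-hat > 1.01 for:", paste(flagged, collapse = ", ")),
                 "")
    lines <- c(lines, "## Diagnostics appendix", "")
    for (nm in names(diagnostics)) {
      d <- diagnostics[[nm]]
      lines <- c(lines, paste0("### ", nm), "",
                 "| parameter | R-hat | bulk ESS |", "|---|---|---|",
                 sprintf("| %s | %.4f | %.0f |", d$table$parameter,
                         d$table$rhat, d$table$ess_bulk),
                 "", sprintf("Post-warmup divergences: %d.", d$divergences),
                 "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
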
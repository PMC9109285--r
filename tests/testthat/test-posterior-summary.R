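# Effect-scale transforms, cumulative probability tables, density export,
# report assembly.

fake_draws <- function(group, kind = "bernoulli_logit", chains = 2) {
  n <- length(group)
  draws <- cbind(`(Intercept)` = rnorm(n), group = group)
  structure(list(draws = draws,
                 chain_id = rep_len(seq_len(chains), n),
                 model_kind = kind, par_names = colnames(draws),
                 n_chains = chains, n_iter = n / chains,
                 diagnostics = NULL, divergences = 0L),
            class = "posterior_draws")
}

test_that("odds-ratio draws are the exponentiated group coefficient", {
  expect_equal(as.numeric(or_samples(fake_draws(rep(0, 10)))), rep(1, 10))
  expect_equal(as.numeric(or_samples(fake_draws(rep(log(0.6), 10)))),
               rep(0.6, 10))
  set.seed(1)
  b2 <- rnorm(5000, -0.4, 0.3)
  or <- or_samples(fake_draws(b2))
  expect_gte(mean(or), exp(mean(b2)))  # Jensen
  expect_error(or_samples(fake_draws(rnorm(10), kind = "gaussian")),
               "Bernoulli")
})

test_that("cumulative probabilities count draws below thresholds", {
  tab <- cumulative_table(c(0.5, 0.7, 0.9, 1.1), 1, "less_than")
  expect_equal(tab$cum_prob, 0.75)
  tab_inf <- cumulative_table(c(0.5, 0.7, 0.9, 1.1), Inf, "less_than")
  expect_equal(tab_inf$cum_prob, 1)
  expect_error(cumulative_table(numeric(0), 1), "empty")
})

test_that("cumulative tables are monotone and identities hold exactly", {
  set.seed(3)
  b2 <- rnorm(4000, -0.45, 0.28)
  or <- exp(b2)
  less <- cumulative_table(or, sort(runif(7, 0.3, 1.5)), "less_than")
  expect_true(all(diff(less$cum_prob) >= 0))
  expect_true(all(less$cum_prob >= 0 & less$cum_prob <= 1))
  expect_lt(less$ci95[1], less$ci95[2])

  red <- cumulative_table(b2, c(0, 0.25, 0.5, 1), "reduction_at_least")
  expect_true(all(diff(red$cum_prob) <= 0))
  # P(OR < 1) on OR draws equals P(beta2 < 0) on the same draws, exactly
  expect_identical(cumulative_table(or, 1, "less_than")$cum_prob,
                   mean(b2 < 0))
  # reduction probabilities are P(beta2 <= -t); magnitudes positive
  expect_identical(red$cum_prob[1], mean(b2 <= 0))
  expect_equal(red$posterior_mean, -mean(b2))
  expect_gt(red$posterior_mean, 0)

  # invariant to chain concatenation order
  perm <- sample(length(or))
  expect_equal(cumulative_table(or[perm], 1, "less_than")$posterior_mean,
               mean(or))
})

test_that("Monte-Carlo SEs are reported and shrink with sample size", {
  set.seed(9)
  small <- cumulative_table(exp(rnorm(500, -0.4, 0.3)), 1, "less_than")
  big <- cumulative_table(exp(rnorm(50000, -0.4, 0.3)), 1, "less_than")
  expect_gt(small$mc_se[1], 0)
  expect_lt(big$mc_se[1], small$mc_se[1])
})

test_that("density export writes a normalized binned density and figure", {
  set.seed(5)
  x <- rnorm(5000)
  fig <- tempfile(fileext = ".png")
  out <- density_export(x, fig, ref_value = 0)
  expect_true(file.exists(fig))
  expect_true(file.exists(out$csv))
  area <- sum(out$bins$density * (out$bins$bin_right - out$bins$bin_left))
  expect_equal(area, 1, tolerance = 0.01)

  # right-skew of exp-transformed normals: modal bin below the mean
  or <- exp(rnorm(20000, -0.4, 0.3))
  out_or <- density_export(or, tempfile(fileext = ".pdf"))
  mode_mid <- out_or$bins$midpoint[which.max(out_or$bins$density)]
  expect_lt(mode_mid, mean(or))

  # degenerate all-equal samples occupy a single bin
  out_deg <- density_export(rep(0.6, 200), tempfile(fileext = ".pdf"))
  expect_equal(sum(out_deg$bins$count > 0), 1)

  expect_error(density_export(rnorm(50), tempfile(fileext = ".png")),
               "at least 100")
})

test_that("report renders three outcome blocks and conditional warnings", {
  set.seed(11)
  tabs <- list(
    cumulative_table(exp(rnorm(1000, -0.4, 0.3)), c(1, 0.8, 0.6),
                     "less_than", outcome = "risk"),
    cumulative_table(rnorm(1000, -0.7, 0.4), c(0, 0.5, 1),
                     "reduction_at_least", outcome = "audit_total"),
    cumulative_table(rnorm(1000, -0.4, 0.2), c(0, 0.25, 0.5),
                     "reduction_at_least", outcome = "audit_c"))
  doc <- effect_report(tabs)
  txt <- paste(doc, collapse = "\n")
  expect_match(txt, "Risky drinking \\(odds ratio\\)")
  expect_match(txt, "AUDIT total score")
  expect_match(txt, "AUDIT-C score")
  expect_no_match(txt, "WARNING")

  flagged <- structure(list(
    table = data.frame(parameter = "group", rhat = 1.2, ess_bulk = 50,
                       flagged = TRUE),
    divergences = 3L, flagged = "group"), class = "mcmc_diagnostics")
  doc2 <- effect_report(tabs, diagnostics = list(risk = flagged))
  expect_match(paste(doc2, collapse = "\n"), "WARNING: convergence flags")

  clean <- structure(list(
    table = data.frame(parameter = "group", rhat = 1.0, ess_bulk = 900,
                       flagged = FALSE),
    divergences = 0L, flagged = character(0)), class = "mcmc_diagnostics")
  doc3 <- effect_report(tabs, diagnostics = list(risk = clean))
  expect_no_match(paste(doc3, collapse = "\n"), "WARNING")

  f <- tempfile(fileext = ".md")
  effect_report(tabs, path = f)
  expect_true(file.exists(f))
})
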
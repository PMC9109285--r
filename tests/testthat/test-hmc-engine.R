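# Sampler correctness against known targets, and diagnostics behavior.

prior_only_model <- function(p = 3) {
  X <- matrix(numeric(0), 0, p)
  colnames(X) <- paste0("b", seq_len(p))
  hb_model(X, y = numeric(0), kind = "bernoulli_logit")
}

test_that("sampler configuration is validated", {
  expect_error(sampler_config(n_chains = 0), "counts")
  expect_error(sampler_config(step_size = -1), "step_size")
  expect_error(sampler_config(target_accept = 1.5), "target_accept")
  cfg <- sampler_config(preset = "per_chain")
  expect_equal(cfg$n_iter, 12500L)
  expect_equal(cfg$warmup, 12500L)
})

test_that("a standard-normal target is recovered to Monte-Carlo accuracy", {
  m <- prior_only_model(3)
  dr <- hmc_sample(m, test_sampler(seed = 4, n_chains = 4, n_iter = 1000,
                                   warmup = 500))
  expect_equal(nrow(dr$draws), 4000)
  for (j in seq_len(3)) {
    x <- dr$draws[, j]
    ess <- dr$diagnostics$ess_bulk[j]
    expect_lt(abs(mean(x)), 4 / sqrt(ess))
    expect_lt(abs(var(x) - 1), 0.1)
  }
})

test_that("posterior tail probability matches 2-D grid integration", {
  fx <- fixture_logistic_12()
  X <- cbind(`(Intercept)` = 1, x = fx$x)
  m <- hb_model(X, y = fx$y, kind = "bernoulli_logit")
  p_grid <- grid_p_slope_neg(fx$x, fx$y)
  dr <- hmc_sample(m, test_sampler(seed = 2, n_chains = 4, n_iter = 1500,
                                   warmup = 500))
  ind <- as.numeric(dr$draws[, "x"] < 0)
  p_hmc <- mean(ind)
  mcse <- sqrt(p_hmc * (1 - p_hmc) / auditbi:::ess_single(ind))
  expect_lt(abs(p_hmc - p_grid), 3 * mcse)
})

test_that("independent seeds agree within Monte-Carlo error", {
  trial <- simulate_trial(sim_config(seed = 23, n_per_arm = c(150, 150)))
  m <- hb_model(encode_design(trial$table, "risk"))
  p_or <- function(seed) {
    dr <- hmc_sample(m, test_sampler(seed = seed, n_chains = 2,
                                     n_iter = 800, warmup = 500))
    ind <- as.numeric(or_samples(dr) < 1)
    c(p = mean(ind), se = sqrt(mean(ind) * (1 - mean(ind)) /
                                 auditbi:::ess_single(ind)))
  }
  a <- p_or(101); b <- p_or(202)
  expect_lt(abs(a["p"] - b["p"]), 3 * sqrt(a["se"]^2 + b["se"]^2))
})

test_that("sampling is reproducible given the seed", {
  m <- prior_only_model(2)
  d1 <- hmc_sample(m, test_sampler(seed = 9, n_chains = 2, n_iter = 200,
                                   warmup = 200))
  d2 <- hmc_sample(m, test_sampler(seed = 9, n_chains = 2, n_iter = 200,
                                   warmup = 200))
  expect_identical(d1$draws, d2$draws)
})

test_that("empirical covariance of a 2-D Gaussian target is near-identity", {
  m <- prior_only_model(2)
  dr <- hmc_sample(m, sampler_config(n_chains = 4, n_iter = 10000,
                                     warmup = 500, seed = 6))
  S <- cov(dr$draws)
  err <- norm(S - diag(2), "F") / norm(diag(2), "F")
  expect_lt(err, 0.05)
})

test_that("centered and non-centered parameterizations agree", {
  trial <- simulate_trial(sim_config(seed = 29, n_per_arm = c(120, 120)))
  des <- encode_design(trial$table, "risk")
  p_b2_neg <- function(par) {
    m <- hb_model(des, parameterization = par)
    dr <- hmc_sample(m, test_sampler(seed = 31, n_chains = 2,
                                     n_iter = 1000, warmup = 600))
    ind <- as.numeric(dr$draws[, "group"] < 0)
    c(p = mean(ind), se = sqrt(mean(ind) * (1 - mean(ind)) /
                                 auditbi:::ess_single(ind)))
  }
  a <- p_b2_neg("noncentered"); b <- p_b2_neg("centered")
  expect_lt(abs(a["p"] - b["p"]), 3 * sqrt(a["se"]^2 + b["se"]^2))
})

test_that("diagnostics separate exchangeable from divergent chains", {
  set.seed(77)
  n <- 500
  good <- matrix(rnorm(4 * n), n, 4)
  rhat_good <- auditbi:::rhat_core(auditbi:::split_chains(
    auditbi:::rank_normalize(good)))
  expect_gt(rhat_good, 0.99)
  expect_lt(rhat_good, 1.01)

  shifted <- cbind(matrix(rnorm(3 * n), n, 3), rnorm(n, 5))
  rhat_bad <- auditbi:::rhat_core(auditbi:::split_chains(
    auditbi:::rank_normalize(shifted)))
  expect_gt(rhat_bad, 1.5)

  # ESS of white noise is close to the number of draws
  ess <- auditbi:::ess_core(auditbi:::split_chains(good))
  expect_lt(abs(ess - 4 * n) / (4 * n), 0.2)
})

test_that("diagnose flags constructed non-convergence on draws objects", {
  m <- prior_only_model(1)
  dr <- hmc_sample(m, test_sampler(seed = 3, n_chains = 4, n_iter = 300,
                                   warmup = 300))
  # graft a shifted chain onto the draws to force disagreement
  dr$draws[dr$chain_id == 4, 1] <- dr$draws[dr$chain_id == 4, 1] + 5
  dr$diagnostics <- NULL
  d <- mcmc_diagnostics(dr)
  expect_true("b1" %in% d$flagged)

  single <- hmc_sample(m, sampler_config(n_chains = 1, n_iter = 200,
                                         warmup = 200, seed = 5))
  expect_error(mcmc_diagnostics(single), "single chain")
})

test_that("draws CSV round-trips with chain and iteration labels", {
  m <- prior_only_model(2)
  dr <- hmc_sample(m, test_sampler(seed = 1, n_chains = 2, n_iter = 150,
                                   warmup = 150))
  f <- tempfile(fileext = ".csv")
  write_draws_csv(dr, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), 300)
  expect_equal(unique(back$chain), c(1, 2))
  expect_equal(max(back$iteration), 150)
  expect_equal(back$b1, unname(dr$draws[, "b1"]), tolerance = 1e-12)
})
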
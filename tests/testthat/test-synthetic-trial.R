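# Synthetic-trial generator: design emulation, determinism, calibration.

test_that("config validation names the offending field", {
  expect_error(sim_config(n_per_arm = c(0, 168)), "n_per_arm")
  expect_error(sim_config(n_centers = 0), "n_centers")
  expect_error(sim_config(attrition_rate = 1.2), "attrition_rate")
  expect_error(sim_config(residual_sd = 0), "residual_sd")
  expect_error(sim_config(baseline_range = c(12, 8)), "baseline_range")
  expect_error(sim_config(baseline_range = c(8, 45)), "baseline_range")
})

test_that("default design matches the emulated trial structure", {
  trial <- simulate_trial(sim_config(seed = 11))
  tab <- trial$table
  expect_equal(nrow(tab), 342)
  expect_equal(sum(tab$arm == "bi"), 174)
  expect_equal(sum(tab$arm == "control"), 168)
  expect_equal(length(unique(tab$center)), 5)
  expect_length(trial$truth$center_intercepts, 5)
  expect_true(all(tab$audit_total_baseline >= 8 &
                    tab$audit_total_baseline <= 15))
  # instrument ranges and internal consistency
  comp <- tab[tab$completed == 1, ]
  expect_true(all(comp$audit_total_fu >= 0 & comp$audit_total_fu <= 40))
  expect_true(all(comp$audit_c_fu >= 0 & comp$audit_c_fu <= 12))
  expect_true(all(comp$audit_c_fu <= comp$audit_total_fu))
  expect_true(all(tab$audit_c_baseline <= tab$audit_total_baseline))
  expect_true(all(is.na(tab$audit_total_fu[tab$completed == 0])))
})

test_that("attrition controls completion flags", {
  none <- simulate_trial(sim_config(attrition_rate = 0, seed = 2))
  expect_true(all(none$table$completed == 1))
  all_out <- simulate_trial(sim_config(attrition_rate = 1, seed = 2))
  expect_true(all(all_out$table$completed == 0))
})

test_that("CSV output is deterministic, line-counted and round-trips", {
  trial <- simulate_trial(sim_config(seed = 5))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_csv(trial, f1)
  write_trial_csv(simulate_trial(sim_config(seed = 5)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_length(readLines(f1), 343)  # header + 342 rows

  back <- read_trial_csv(f1)
  expect_equal(back$id, as.character(trial$table$id))
  for (col in setdiff(names(trial$table), "id"))
    expect_equal(back[[col]], trial$table[[col]], ignore_attr = TRUE)

  # header-only file for an empty table
  f3 <- tempfile(fileext = ".csv")
  write_trial_csv(trial$table[0, ], f3)
  expect_length(readLines(f3), 1)
})

test_that("null effect gives near-identical arm-wise risky proportions", {
  cfg <- sim_config(n_per_arm = c(10000, 10000), true_log_or = 0,
                    sigma_c_true = 0,
                    fixed_effects = c(intercept = 0, sex = 0,
                                      edu_complete = 0, edu_superior = 0,
                                      age = 0),
                    attrition_rate = 0, outcome_mode = "independent",
                    seed = 9)
  tab <- simulate_trial(cfg)$table
  risky <- tab$audit_total_fu >= 8
  p_bi <- mean(risky[tab$arm == "bi"])
  p_ctrl <- mean(risky[tab$arm == "control"])
  expect_lt(abs(p_bi - p_ctrl), 0.02)
})

test_that("pooled risky rate is calibrated to inverse-logit(intercept)", {
  b1 <- 0.5
  cfg <- sim_config(n_per_arm = c(10000, 10000), true_log_or = 0,
                    sigma_c_true = 0,
                    fixed_effects = c(intercept = b1, sex = 0,
                                      edu_complete = 0, edu_superior = 0,
                                      age = 0),
                    attrition_rate = 0, outcome_mode = "independent",
                    seed = 13)
  tab <- simulate_trial(cfg)$table
  p <- plogis(b1)
  se <- sqrt(p * (1 - p) / nrow(tab))
  expect_lt(abs(mean(tab$audit_total_fu >= 8) - p), 3 * se)
})

test_that("lowering the true log-OR lowers the intervention risky rate", {
  mk <- function(lor) {
    cfg <- sim_config(n_per_arm = c(50000, 50000), true_log_or = lor,
                      attrition_rate = 0, outcome_mode = "independent",
                      seed = 21)
    tab <- simulate_trial(cfg)$table
    mean(tab$audit_total_fu[tab$arm == "bi"] >= 8)
  }
  expect_lt(mk(log(0.6)), mk(0))
  expect_lt(mk(log(0.3)), mk(log(0.6)))
})

test_that("independent mode makes the Bernoulli-logit model exactly true", {
  # the encoded binary outcome must reproduce the logistic draw
  cfg <- sim_config(n_per_arm = c(2000, 2000), attrition_rate = 0,
                    outcome_mode = "independent", seed = 31)
  trial <- simulate_trial(cfg)
  tab <- trial$table
  fe <- cfg$fixed_effects
  u <- trial$truth$center_intercepts
  eta <- fe["intercept"] + cfg$true_log_or * (tab$arm == "bi") +
    fe["sex"] * (tab$sex == "female") +
    fe["edu_complete"] * (tab$education == "complete") +
    fe["edu_superior"] * (tab$education == "superior") +
    fe["age"] * tab$age + u[as.integer(sub("C", "", tab$center))]
  # rate matches the model-implied rate within binomial error
  p_hat <- mean(tab$audit_total_fu >= 8)
  p_mod <- mean(plogis(eta))
  expect_lt(abs(p_hat - p_mod), 3 * sqrt(p_mod * (1 - p_mod) / nrow(tab)))
})
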
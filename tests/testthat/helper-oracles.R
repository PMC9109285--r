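# Independent oracles used to check the package implementation. These are
# deliberately written the slow, direct way (scalar loops, textbook
# formulas) and share no code with the package internals.

# Term-by-term log-posterior: likelihood row by row, prior term by term.
oracle_log_posterior <- function(model, theta) {
  p <- model$p; k <- model$k
  beta <- theta[1:p]
  pos <- p
  c_raw <- NULL; sigma_c <- NULL
  if (k > 0) {
    c_raw <- theta[pos + 1:k]
    sigma_c <- exp(theta[pos + k + 1])
    pos <- pos + k + 1
  }
  sigma <- if (model$kind == "gaussian") exp(theta[pos + 1]) else NULL

  total <- 0
  for (i in seq_len(nrow(model$X))) {
    eta <- 0
    for (j in 1:p) eta <- eta + model$X[i, j] * beta[j]
    if (k > 0) {
      ci <- model$center_index[i]
      eta <- eta + if (model$parameterization == "noncentered")
        sigma_c * c_raw[ci] else c_raw[ci]
    }
    total <- total + if (model$kind == "bernoulli_logit") {
      dbinom(model$y[i], 1, plogis(eta), log = TRUE)
    } else {
      dnorm(model$y[i], eta, sigma, log = TRUE)
    }
  }
  for (j in 1:p) total <- total + dnorm(beta[j], 0, model$prior_sd_beta,
                                        log = TRUE)
  if (k > 0) {
    for (j in 1:k) total <- total +
      if (model$parameterization == "noncentered")
        dnorm(c_raw[j], 0, 1, log = TRUE)
      else dnorm(c_raw[j], 0, sigma_c, log = TRUE)
    total <- total + log(2) + dnorm(sigma_c, 0, model$prior_sd_scales,
                                    log = TRUE) + log(sigma_c)
  }
  if (model$kind == "gaussian")
    total <- total + log(2) + dnorm(sigma, 0, model$prior_sd_scales,
                                    log = TRUE) + log(sigma)
  total
}

# Central finite differences of the package log-posterior.
fd_gradient <- function(model, theta, h = 1e-5) {
  sapply(seq_along(theta), function(j) {
    e <- numeric(length(theta)); e[j] <- h
    (log_posterior(model, theta + e) - log_posterior(model, theta - e)) /
      (2 * h)
  })
}

# Hand-rolled iteratively reweighted least squares for ML logistic
# regression (no glm).
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

# P(slope < 0) for a 2-parameter logistic posterior (intercept + one
# covariate, N(0,1) priors) by dense grid integration (Simpson weights).
grid_p_slope_neg <- function(x, y, lim = 8, n_grid = 401) {
  g <- seq(-lim, lim, length.out = n_grid)
  lp <- outer(g, g, Vectorize(function(b1, b2) {
    eta <- b1 + b2 * x
    sum(y * eta - log1p(exp(eta))) + dnorm(b1, log = TRUE) +
      dnorm(b2, log = TRUE)
  }))
  w <- rep(c(2, 4), length.out = n_grid); w[1] <- 1; w[n_grid] <- 1
  W <- outer(w, w)
  post <- exp(lp - max(lp)) * W
  (sum(post[, g < 0]) + 0.5 * sum(post[, g == 0])) / sum(post)
}

# Small deterministic fixture for the sampler-vs-quadrature check:
# a 12-row single-covariate logistic dataset.
fixture_logistic_12 <- function() {
  list(
    x = c(-1.8, -1.2, -0.9, -0.5, -0.2, 0.0, 0.1, 0.4, 0.8, 1.1, 1.5, 2.0),
    y = c(1, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0)
  )
}

# Quick sampler settings for tests.
test_sampler <- function(seed = 1L, n_chains = 2L, n_iter = 500L,
                         warmup = 500L, ...) {
  sampler_config(n_chains = n_chains, n_iter = n_iter, warmup = warmup,
                 seed = seed, ...)
}

# Small complete trial table built by hand (no generator involved).
tiny_trial_table <- function() {
  data.frame(
    id = as.character(1:8),
    center = c("A", "A", "B", "B", "A", "B", "A", "B"),
    arm = c("bi", "control", "bi", "control", "bi", "control", "bi",
            "control"),
    sex = c("male", "female", "female", "male", "male", "female", "female",
            "male"),
    education = c("incomplete", "complete", "superior", "incomplete",
                  "complete", "superior", "incomplete", "complete"),
    age = c(25, 34, 41, 52, 29, 60, 37, 45),
    audit_total_baseline = c(8L, 10L, 12L, 15L, 9L, 11L, 13L, 14L),
    audit_c_baseline = c(5L, 6L, 7L, 8L, 5L, 6L, 7L, 8L),
    audit_total_fu = c(6L, 9L, 7L, 12L, 8L, 5L, 10L, 13L),
    audit_c_fu = c(3L, 5L, 4L, 7L, 5L, 3L, 6L, 8L),
    completed = rep(1L, 8),
    stringsAsFactors = FALSE
  )
}
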
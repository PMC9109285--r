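#' Hierarchical outcome model for a two-arm cluster trial
#'
#' Constructs the Bernoulli-logit or Gaussian outcome model with
#' health-center random intercepts whose log-posterior and analytic
#' gradient drive the HMC sampler. The linear predictor for participant
#' \eqn{i} is \eqn{x_i^T\beta + C_{center(i)}}, with weakly-informative
#' priors centered on the null: \eqn{\beta_j \sim N(0, \code{prior_sd_beta})},
#' \eqn{C_j \sim N(0, \sigma_c)}, and half-normal
#' \eqn{N^+(0, \code{prior_sd_scales})} priors on the scales
#' \eqn{\sigma_c} (center SD) and, for the Gaussian model, the residual SD
#' \eqn{\sigma}.
#'
#' Scales are sampled on the log scale (with the Jacobian included in the
#' posterior). By default the random intercepts use the non-centered
#' parameterization \eqn{C = \sigma_c \cdot c_{raw}},
#' \eqn{c_{raw,j} \sim N(0,1)}, which avoids the funnel geometry that a
#' handful of centers with a weakly identified scale otherwise produces;
#' the centered parameterization is available and induces the same
#' posterior.
#'
#' @param design An [encode_design()] object, or a numeric matrix `X`
#'   (then `y` is required).
#' @param y Outcome vector when `design` is a bare matrix.
#' @param center_index Integer cluster index 1..k when `design` is a bare
#'   matrix; `NULL` drops the random-intercept block entirely.
#' @param kind `"bernoulli_logit"` or `"gaussian"`; inferred from an
#'   `encoded_design`'s outcome when not given.
#' @param prior_sd_beta Prior SD of the regression coefficients.
#' @param prior_sd_scales Scale of the half-normal priors on SDs.
#' @param parameterization `"noncentered"` (default) or `"centered"`
#'   random-intercept parameterization.
#' @return An object of class `hb_model`.
#' @seealso [log_posterior()], [grad_log_posterior()], [hmc_sample()]
#' @export
hb_model <- function(design, y = NULL, center_index = NULL, kind = NULL,
                     prior_sd_beta = 1, prior_sd_scales = 1,
                     parameterization = c("noncentered", "centered")) {
  parameterization <- match.arg(parameterization)
  if (inherits(design, "encoded_design")) {
    X <- design$X
    y <- design$y
    center_index <- design$center_index
    if (is.null(kind))
      kind <- if (design$outcome == "risk") "bernoulli_logit" else "gaussian"
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("`y` is required when `design` is a matrix",
                         call. = FALSE)
    if (is.null(kind)) stop("`kind` is required when `design` is a matrix",
                            call. = FALSE)
  }
  kind <- match.arg(kind, c("bernoulli_logit", "gaussian"))
  if (prior_sd_beta <= 0 || prior_sd_scales <= 0)
    stop("prior SDs must be positive", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (kind == "bernoulli_logit" && length(y) && !all(y %in% c(0, 1)))
    stop("bernoulli_logit outcome must be 0/1", call. = FALSE)
  k <- 0L
  if (!is.null(center_index)) {
    center_index <- as.integer(center_index)
    k <- max(center_index, 0L)
    if (length(center_index) != nrow(X) ||
        (length(center_index) && !setequal(unique(center_index), seq_len(k))))
      stop("center_index must map rows to consecutive integers 1..k",
           call. = FALSE)
  }
  p <- ncol(X)
  dim <- p + (if (k > 0) k + 1L else 0L) + (kind == "gaussian")
  nm <- colnames(X) %||% paste0("beta", seq_len(p))
  par_names <- c(nm,
                 if (k > 0) paste0("C", seq_len(k)),
                 if (k > 0) "sigma_c",
                 if (kind == "gaussian") "sigma")
  structure(list(X = X, y = as.numeric(y), center_index = center_index,
                 kind = kind, k = k, p = p, dim = dim,
                 prior_sd_beta = prior_sd_beta,
                 prior_sd_scales = prior_sd_scales,
                 parameterization = parameterization,
                 par_names = par_names),
            class = "hb_model")
}

#' @export
print.hb_model <- function(x, ...) {
  cat(sprintf("Hierarchical %s model: n = %d, p = %d fixed effects, k = %d centers (%s), dim = %d\n",
              x$kind, nrow(x$X), x$p, x$k, x$parameterization, x$dim))
  invisible(x)
}

check_theta <- function(model, theta) {
  if (length(theta) != model$dim)
    stop(sprintf("theta has length %d but the model is %d-dimensional",
                 length(theta), model$dim), call. = FALSE)
}

# Unpack the unconstrained vector into named components.
split_theta <- function(model, theta) {
  p <- model$p; k <- model$k
  out <- list(beta = theta[seq_len(p)])
  pos <- p
  if (k > 0) {
    out$ranef <- theta[pos + seq_len(k)]       # c_raw or C
    out$log_sigma_c <- theta[pos + k + 1]
    pos <- pos + k + 1
  }
  if (model$kind == "gaussian") out$log_sigma <- theta[pos + 1]
  out
}

linpred <- function(model, th) {
  eta <- drop(model$X %*% th$beta)
  if (model$k > 0) {
    C <- if (model$parameterization == "noncentered")
      exp(th$log_sigma_c) * th$ranef else th$ranef
    eta <- eta + C[model$center_index]
  }
  eta
}

# log half-normal density of s = exp(z) with scale `sd`, plus the Jacobian
# of the log transform.
halfnorm_log_jac <- function(z, sd) {
  s <- exp(z)
  log(2) + stats::dnorm(s, 0, sd, log = TRUE) + z
}

#' Log-likelihood of a hierarchical trial model
#'
#' @param model An [hb_model()].
#' @param theta Unconstrained parameter vector (coefficients, random
#'   effects, log scales).
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(model, theta) {
  check_theta(model, theta)
  th <- split_theta(model, theta)
  if (nrow(model$X) == 0) return(0)
  eta <- linpred(model, th)
  if (model$kind == "bernoulli_logit") {
    sum(model$y * eta - log1pexp(eta))
  } else {
    sigma <- exp(th$log_sigma)
    n <- length(model$y)
    -n * log(sigma) - sum((model$y - eta)^2) / (2 * sigma^2) -
      n / 2 * log(2 * pi)
  }
}

#' Log-prior of a hierarchical trial model
#'
#' Includes the Jacobian terms of the log-scale transforms, so that
#' [log_posterior()] is the exact unnormalized posterior density on the
#' unconstrained space.
#'
#' @inheritParams log_likelihood
#' @return The log-prior (a scalar).
#' @export
log_prior <- function(model, theta) {
  check_theta(model, theta)
  th <- split_theta(model, theta)
  lp <- sum(stats::dnorm(th$beta, 0, model$prior_sd_beta, log = TRUE))
  if (model$k > 0) {
    if (model$parameterization == "noncentered") {
      lp <- lp + sum(stats::dnorm(th$ranef, 0, 1, log = TRUE))
    } else {
      sigma_c <- exp(th$log_sigma_c)
      lp <- lp + sum(stats::dnorm(th$ranef, 0, sigma_c, log = TRUE))
    }
    lp <- lp + halfnorm_log_jac(th$log_sigma_c, model$prior_sd_scales)
  }
  if (model$kind == "gaussian")
    lp <- lp + halfnorm_log_jac(th$log_sigma, model$prior_sd_scales)
  lp
}

#' Log-posterior density (unnormalized, unconstrained space)
#'
#' @inheritParams log_likelihood
#' @return `log_likelihood(model, theta) + log_prior(model, theta)`.
#' @export
log_posterior <- function(model, theta) {
  log_likelihood(model, theta) + log_prior(model, theta)
}

#' Analytic gradient of the log-posterior
#'
#' Exact gradient in the unconstrained parameterization (chain rule through
#' the non-centered scaling and the log-scale transforms included), as
#' required by Hamiltonian Monte Carlo.
#'
#' @inheritParams log_likelihood
#' @return Numeric vector of length `model$dim`.
#' @export
grad_log_posterior <- function(model, theta) {
  check_theta(model, theta)
  th <- split_theta(model, theta)
  p <- model$p; k <- model$k
  g <- numeric(model$dim)
  n <- nrow(model$X)

  if (n > 0) {
    eta <- linpred(model, th)
    if (model$kind == "bernoulli_logit") {
      r <- model$y - stats::plogis(eta)       # d loglik / d eta
    } else {
      sigma <- exp(th$log_sigma)
      r <- (model$y - eta) / sigma^2
    }
    g[seq_len(p)] <- drop(crossprod(model$X, r))
    if (k > 0) {
      gsum <- as.numeric(rowsum(r, model$center_index)[, 1])
      sigma_c <- exp(th$log_sigma_c)
      if (model$parameterization == "noncentered") {
        g[p + seq_len(k)] <- sigma_c * gsum
        g[p + k + 1] <- sigma_c * sum(gsum * th$ranef)
      } else {
        g[p + seq_len(k)] <- gsum
      }
    }
    if (model$kind == "gaussian") {
      sigma <- exp(th$log_sigma)
      g[model$dim] <- -n + sum((model$y - eta)^2) / sigma^2
    }
  }

  # prior terms
  g[seq_len(p)] <- g[seq_len(p)] - th$beta / model$prior_sd_beta^2
  if (k > 0) {
    sigma_c <- exp(th$log_sigma_c)
    s2 <- model$prior_sd_scales^2
    if (model$parameterization == "noncentered") {
      g[p + seq_len(k)] <- g[p + seq_len(k)] - th$ranef
      g[p + k + 1] <- g[p + k + 1] + 1 - sigma_c^2 / s2
    } else {
      g[p + seq_len(k)] <- g[p + seq_len(k)] - th$ranef / sigma_c^2
      g[p + k + 1] <- g[p + k + 1] - k + sum(th$ranef^2) / sigma_c^2 +
        1 - sigma_c^2 / s2
    }
  }
  if (model$kind == "gaussian") {
    sigma <- exp(th$log_sigma)
    g[model$dim] <- g[model$dim] + 1 - sigma^2 / model$prior_sd_scales^2
  }
  g
}

# Map a matrix of unconstrained draws to the constrained, named scale:
# betas unchanged, C = sigma_c * c_raw (non-centered) or as-is (centered),
# sigma_c and sigma exponentiated.
constrain_draws <- function(model, draws) {
  p <- model$p; k <- model$k
  out <- draws
  if (k > 0) {
    sigma_c <- exp(draws[, p + k + 1])
    if (model$parameterization == "noncentered")
      out[, p + seq_len(k)] <- draws[, p + seq_len(k), drop = FALSE] * sigma_c
    out[, p + k + 1] <- sigma_c
  }
  if (model$kind == "gaussian") out[, model$dim] <- exp(draws[, model$dim])
  colnames(out) <- model$par_names
  out
}
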
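#' Sampler configuration for Hamiltonian Monte Carlo
#'
#' Defaults mirror the original run configuration read as totals split
#' across chains: four chains with 6,250 warmup and 6,250 kept iterations
#' each (50,000 iterations in total, 25,000 of them warmup). Monte-Carlo
#' error at these settings is far below two-decimal reporting precision.
#'
#' @param n_chains Number of chains.
#' @param n_iter Kept (post-warmup) iterations per chain.
#' @param warmup Warmup iterations per chain (step-size and mass-matrix
#'   adaptation happen here; warmup draws are discarded).
#' @param step_size Leapfrog step size, or `NULL` to determine it
#'   automatically (heuristic initialization + dual-averaging adaptation to
#'   `target_accept`).
#' @param n_leapfrog Base number of leapfrog steps, or `NULL` to target an
#'   integration time of `int_time` (the per-iteration count is jittered
#'   uniformly between 50\% and 150\% of the base to break periodicity).
#' @param int_time Trajectory integration time used when `n_leapfrog` is
#'   automatic.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param preset `"default"` (as above), `"per_chain"` (12,500 warmup +
#'   12,500 kept per chain, the per-chain reading of the original
#'   configuration), or `"test"` (small, for quick runs).
#' @param seed Integer seed; each chain uses an independent derived stream.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iter = 6250L, warmup = 6250L,
                           step_size = NULL, n_leapfrog = NULL,
                           int_time = 1.2, target_accept = 0.8,
                           preset = c("default", "per_chain", "test"),
                           seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "per_chain") { n_iter <- 12500L; warmup <- 12500L }
  if (preset == "test") { n_iter <- 500L; warmup <- 500L; n_chains <- 2L }
  if (n_chains < 1 || n_iter < 1 || warmup < 1)
    stop_field("n_chains/n_iter/warmup", "all counts must be >= 1")
  if (!is.null(step_size) && step_size <= 0)
    stop_field("step_size", "must be positive")
  if (!is.null(n_leapfrog) && n_leapfrog < 1)
    stop_field("n_leapfrog", "must be >= 1")
  if (target_accept <= 0 || target_accept >= 1)
    stop_field("target_accept", "must be in (0, 1)")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 warmup = as.integer(warmup),
                 step_size = step_size, n_leapfrog = n_leapfrog,
                 int_time = int_time, target_accept = target_accept,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# One leapfrog trajectory. Returns the proposal, its log-posterior and the
# energy difference; flags divergence on non-finite or exploding energy.
leapfrog <- function(model, theta, momentum, eps, L, inv_mass) {
  lp_fun <- function(t) log_posterior(model, t)
  gr <- grad_log_posterior(model, theta)
  p <- momentum + 0.5 * eps * gr
  t_new <- theta
  for (l in seq_len(L)) {
    t_new <- t_new + eps * (inv_mass * p)
    gr <- grad_log_posterior(model, t_new)
    if (any(!is.finite(gr))) return(list(divergent = TRUE))
    p <- p + eps * gr * (if (l < L) 1 else 0.5)
  }
  lp_new <- lp_fun(t_new)
  if (!is.finite(lp_new)) return(list(divergent = TRUE))
  list(theta = t_new, momentum = p, lp = lp_new, divergent = FALSE)
}

# Heuristic initial step size (double/halve until the one-step acceptance
# probability crosses 0.5).
find_reasonable_epsilon <- function(model, theta, inv_mass) {
  eps <- 0.1
  lp0 <- log_posterior(model, theta)
  energy <- function(eps) {
    p0 <- stats::rnorm(length(theta), 0, sqrt(1 / inv_mass))
    step <- leapfrog(model, theta, p0, eps, 1L, inv_mass)
    if (isTRUE(step$divergent)) return(-Inf)
    (step$lp - 0.5 * sum(step$momentum^2 * inv_mass)) -
      (lp0 - 0.5 * sum(p0^2 * inv_mass))
  }
  dH <- energy(eps)
  dir <- if (is.finite(dH) && dH > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps2 <- eps * 2^dir
    dH <- energy(eps2)
    cross <- if (dir == 1) !(is.finite(dH) && dH > log(0.5))
             else (is.finite(dH) && dH > log(0.5))
    if (cross) break
    eps <- eps2
  }
  eps
}

run_chain <- function(model, config, chain_seed) {
  with_seed(chain_seed, {
    dim <- model$dim
    target <- config$target_accept

    theta <- NULL
    for (try in 1:100) {
      cand <- stats::runif(dim, -2, 2)
      if (is.finite(log_posterior(model, cand))) { theta <- cand; break }
    }
    if (is.null(theta))
      stop("could not initialize chain: log-posterior non-finite after 100 jittered tries",
           call. = FALSE)

    inv_mass <- rep(1, dim)
    adapt_eps <- is.null(config$step_size)
    eps <- config$step_size %||% find_reasonable_epsilon(model, theta, inv_mass)

    # dual-averaging state (reset when the mass matrix changes)
    da_init <- function(eps) list(mu = log(10 * eps), log_eps_bar = 0,
                                  H_bar = 0, t = 0)
    da <- da_init(eps)
    da_update <- function(da, accept_prob) {
      da$t <- da$t + 1
      gamma <- 0.05; t0 <- 10; kappa <- 0.75
      da$H_bar <- (1 - 1 / (da$t + t0)) * da$H_bar +
        (target - accept_prob) / (da$t + t0)
      log_eps <- da$mu - sqrt(da$t) / gamma * da$H_bar
      w <- da$t^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      da$eps <- exp(log_eps)
      da
    }

    n_total <- config$warmup + config$n_iter
    # Warmup schedule: an eps-only buffer, two mass-estimation windows
    # (each ends with a diagonal-mass update from its own draws and a
    # step-size re-initialization), and a final eps-only buffer.
    w <- config$warmup
    buf1 <- max(1L, floor(0.10 * w))
    win_a_end <- buf1 + max(1L, floor(0.25 * w))
    win_b_end <- win_a_end + max(1L, floor(0.45 * w))
    win_starts <- c(buf1 + 1L, win_a_end + 1L)
    win_ends <- c(win_a_end, win_b_end)
    win_draws <- NULL

    draws <- matrix(NA_real_, config$n_iter, dim)
    accept_sum <- 0
    div_warm <- 0L; div_kept <- 0L
    mass_adapted <- FALSE
    lp0 <- log_posterior(model, theta)

    base_L <- function(eps) {
      if (!is.null(config$n_leapfrog)) return(config$n_leapfrog)
      cap <- if (mass_adapted) 500L else 50L
      min(cap, max(1L, as.integer(round(config$int_time / eps))))
    }

    for (it in seq_len(n_total)) {
      warm <- it <= config$warmup
      Lb <- base_L(eps)
      L <- sample(seq(max(1L, floor(0.5 * Lb)),
                      max(1L, ceiling(1.5 * Lb))), 1L)
      p0 <- stats::rnorm(dim, 0, sqrt(1 / inv_mass))
      H0 <- lp0 - 0.5 * sum(p0^2 * inv_mass)
      step <- leapfrog(model, theta, p0, eps, L, inv_mass)
      if (isTRUE(step$divergent)) {
        accept_prob <- 0
        if (warm) div_warm <- div_warm + 1L else div_kept <- div_kept + 1L
      } else {
        H1 <- step$lp - 0.5 * sum(step$momentum^2 * inv_mass)
        dH <- H1 - H0
        if (!is.finite(dH) || dH < -1000) {
          accept_prob <- 0
          if (warm) div_warm <- div_warm + 1L else div_kept <- div_kept + 1L
        } else {
          accept_prob <- min(1, exp(dH))
          if (log(stats::runif(1)) < dH) { theta <- step$theta; lp0 <- step$lp }
        }
      }

      if (warm) {
        if (adapt_eps) { da <- da_update(da, accept_prob); eps <- da$eps }
        in_win <- which(it >= win_starts & it <= win_ends)
        if (length(in_win)) {
          win_draws <- rbind(win_draws, theta)
          if (it == win_ends[in_win]) {
            # diagonal mass = regularized marginal variances of the window
            v <- apply(win_draws, 2, stats::var)
            m <- nrow(win_draws)
            v <- v * m / (m + 5) + 1e-3 * 5 / (m + 5)
            v[!is.finite(v) | v <= 0] <- 1
            inv_mass <- v                    # inverse mass = posterior var
            mass_adapted <- TRUE
            win_draws <- NULL
            if (adapt_eps) {
              eps <- find_reasonable_epsilon(model, theta, inv_mass)
              da <- da_init(eps)
            }
          }
        }
        if (it == config$warmup && adapt_eps) eps <- exp(da$log_eps_bar)
      } else {
        draws[it - config$warmup, ] <- theta
        accept_sum <- accept_sum + accept_prob
      }
    }

    if (div_kept >= config$n_iter)
      stop("sampling failure: every post-warmup iteration diverged",
           call. = FALSE)

    list(draws = draws, eps = eps, inv_mass = inv_mass,
         accept_rate = accept_sum / config$n_iter,
         divergences = div_kept, divergences_warmup = div_warm)
  })
}

#' Sample from a hierarchical trial model with HMC
#'
#' Plain Hamiltonian Monte Carlo with leapfrog integration and a
#' Metropolis correction. During warmup the step size is adapted to the
#' target acceptance statistic by dual averaging and a diagonal mass
#' matrix is estimated from early warmup draws; both are frozen for the
#' kept iterations. The leapfrog count is jittered every iteration.
#' Sampling is reproducible given `(seed, chain)`.
#'
#' @param model An [hb_model()].
#' @param config A [sampler_config()].
#' @return An object of class `posterior_draws`: list with `draws` (kept
#'   draws x named constrained parameters: coefficients, center effects
#'   `C1..Ck`, `sigma_c`, and `sigma` for Gaussian models), `chain_id`,
#'   `diagnostics` (split-R-hat and bulk-ESS per parameter, see
#'   [mcmc_diagnostics()]), `divergences`, and per-chain sampler info.
#' @export
hmc_sample <- function(model, config = sampler_config()) {
  stopifnot(inherits(model, "hb_model"), inherits(config, "sampler_config"))
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_chain(model, config, derive_seed(config$seed, ch))
  })
  raw <- do.call(rbind, lapply(chains, `[[`, "draws"))
  draws <- constrain_draws(model, raw)
  chain_id <- rep(seq_len(config$n_chains), each = config$n_iter)
  divergences <- sum(vapply(chains, `[[`, 0L, "divergences"))
  diagnostics <- if (config$n_chains >= 2 && config$n_iter >= 4) {
    diag_table(draws, chain_id)
  } else NULL
  structure(list(
    draws = draws,
    chain_id = chain_id,
    model_kind = model$kind,
    par_names = model$par_names,
    n_chains = config$n_chains,
    n_iter = config$n_iter,
    diagnostics = diagnostics,
    divergences = divergences,
    divergences_warmup = sum(vapply(chains, `[[`, 0L, "divergences_warmup")),
    accept_rate = vapply(chains, `[[`, 0, "accept_rate"),
    step_size = vapply(chains, `[[`, 0, "eps"),
    config = config
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d iterations, %d parameters (%s model)\n",
              x$n_chains, x$n_iter, ncol(x$draws), x$model_kind))
  cat(sprintf("  mean acceptance %.2f, %d post-warmup divergences\n",
              mean(x$accept_rate), x$divergences))
  if (!is.null(x$diagnostics)) {
    flagged <- x$diagnostics$parameter[x$diagnostics$flagged]
    if (length(flagged))
      cat("  convergence flags (R-hat > 1.01): ",
          paste(flagged, collapse = ", "), "\n")
    else cat("  all split-R-hat <= 1.01\n")
  }
  invisible(x)
}

#' Write posterior draws to CSV
#'
#' One row per kept draw with `chain` and `iteration` columns followed by
#' the named constrained parameters.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- data.frame(chain = draws$chain_id,
                    iteration = sequence(rep(draws$n_iter, draws$n_chains)),
                    draws$draws, check.names = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
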
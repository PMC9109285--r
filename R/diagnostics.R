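# Convergence diagnostics: split-R-hat and bulk effective sample size on
# rank-normalized draws, with Geyer initial-monotone truncation of the
# autocorrelation sum.

# Biased (divide by n) linear autocovariance via FFT zero-padding.
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  M <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, M - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / M
  ac / n
}

# Split each column (chain) into first/second half.
split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  lower <- mat[seq_len(half), , drop = FALSE]
  upper <- mat[(n - half + 1):n, , drop = FALSE]
  cbind(lower, upper)
}

rank_normalize <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

# R-hat and ESS from an iterations x chains matrix (m >= 1).
rhat_core <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (m < 2) return(NA_real_)
  W <- mean(apply(mat, 2, stats::var))
  B_over_n <- stats::var(colMeans(mat))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

ess_core <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  ch_var <- apply(mat, 2, stats::var)
  W <- mean(ch_var)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B_over_n <- if (m > 1) stats::var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  acov <- sapply(seq_len(m), function(j) autocov_fft(mat[, j]))
  mean_acov <- if (m > 1) rowMeans(acov) else as.numeric(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_t <- length(rho) - length(rho) %% 2
  tau <- 0
  prev <- Inf
  for (t in seq(1, max_t - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
  }
  tau <- max(2 * tau - 1, 1e-10)
  n * m / tau
}

# single-sequence ESS (used for Monte-Carlo standard errors)
ess_single <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(NA_real_)
  ess_core(matrix(x, ncol = 1))
}

diag_table <- function(draws, chain_id) {
  chains <- sort(unique(chain_id))
  per <- table(chain_id)
  n <- min(per)
  res <- lapply(colnames(draws), function(par) {
    mat <- sapply(chains, function(ch) draws[chain_id == ch, par][seq_len(n)])
    if (stats::var(as.numeric(mat)) == 0)
      return(data.frame(parameter = par, rhat = NA_real_,
                        ess_bulk = NA_real_, flagged = FALSE))
    z <- rank_normalize(mat)
    zs <- split_chains(z)
    r <- rhat_core(zs)
    data.frame(parameter = par, rhat = r, ess_bulk = ess_core(zs),
               flagged = is.finite(r) && r > 1.01)
  })
  do.call(rbind, res)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes split-R-hat (potential scale reduction on split, rank-normalized
#' chains) and bulk effective sample size per parameter, flags parameters
#' with R-hat > 1.01, and reports the post-warmup divergence count.
#'
#' @param draws A `posterior_draws` object from [hmc_sample()], with at
#'   least two chains.
#' @return A list of class `mcmc_diagnostics` with a per-parameter table
#'   (`parameter`, `rhat`, `ess_bulk`, `flagged`), the divergence count,
#'   and the flagged parameter names.
#' @export
mcmc_diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_chains < 2)
    stop("R-hat is unavailable with a single chain: run at least 2 chains",
         call. = FALSE)
  if (draws$n_iter < 100)
    warning("fewer than 100 kept draws per chain; diagnostics are unstable")
  tab <- draws$diagnostics %||% diag_table(draws$draws, draws$chain_id)
  structure(list(table = tab,
                 divergences = draws$divergences,
                 flagged = tab$parameter[tab$flagged]),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (split-R-hat, bulk ESS)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("post-warmup divergences: %d\n", x$divergences))
  if (length(x$flagged))
    cat("FLAGGED (R-hat > 1.01):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
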
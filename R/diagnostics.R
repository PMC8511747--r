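#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-adjusted sample size using Geyer's initial positive
#' sequence: lag-autocorrelations are summed in adjacent pairs until a pair
#' sum turns non-positive.
#'
#' @param x Numeric vector of draws.
#' @return Effective sample size (capped at `length(x)`); `NA` for a
#'   constant chain.
#' @references Geyer, C.J. (1992) Practical Markov chain Monte Carlo.
#'   Statistical Science 7, 473-483.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 2L, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  min(n / (1 + 2 * s), n)
}

#' Split-chain convergence diagnostic (R-hat)
#'
#' Potential scale reduction factor computed on each chain split in half,
#' comparing between- and within-half variances. Values near 1 indicate the
#' halves agree in location and scale.
#'
#' @param chains A list of numeric vectors (one per chain), or a single
#'   numeric vector (treated as one chain, split in two).
#' @return Split R-hat; `NA` if the draws are constant.
#' @references Gelman, A. & Rubin, D.B. (1992) Inference from iterative
#'   simulation using multiple sequences. Statistical Science 7, 457-472.
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  halves <- unlist(lapply(chains, function(x) {
    n2 <- length(x) %/% 2
    list(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1, length(x))])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}
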
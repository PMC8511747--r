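#' MCMC chain settings for the heritability model
#'
#' @param n_iterations Total Gibbs iterations (default 50000).
#' @param burn_in Iterations discarded before sampling (default 10000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 20, so the
#'   defaults retain exactly 2000 draws per parameter).
#' @param seed Integer seed.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters shared by the
#'   three variance components (default 0.001/0.001, a weakly informative
#'   near-flat prior; fixed effects get an improper flat prior).
#' @param n_chains Number of chains (default 1; use >1 for the split-chain
#'   convergence diagnostic across independently seeded chains).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_iterations = 50000, burn_in = 10000, thin = 20,
                         seed = 1L, prior_shape = 0.001, prior_rate = 0.001,
                         n_chains = 1L) {
  stopifnot(burn_in < n_iterations, thin >= 1, n_chains >= 1,
            prior_shape > 0, prior_rate > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prior_shape = prior_shape,
                 prior_rate = prior_rate, n_chains = as.integer(n_chains)),
            class = "chain_config")
}

#' Retained draws implied by a chain configuration
#' @param config A [chain_config()].
#' @return `floor((n_iterations - burn_in) / thin)` per chain.
#' @export
retained_draws <- function(config) {
  (config$n_iterations - config$burn_in) %/% config$thin
}

# run one chain; returns matrix with columns V_genotype, V_tank, V_residual
# (fixed-effect draws are produced by the sampler but dropped here)
.run_chain <- function(y, X, gidx, tidx, config, seed) {
  set.seed(as.integer(seed))
  draws <- gibbs_varcomp(y, X, gidx, tidx,
                         config$n_iterations, config$burn_in, config$thin,
                         rep(config$prior_shape, 3), rep(config$prior_rate, 3))
  draws <- draws[, 1:3, drop = FALSE]
  colnames(draws) <- c("V_genotype", "V_tank", "V_residual")
  draws
}

#' Bayesian broad-sense heritability of a trait
#'
#' Fits, by Gibbs sampling, the Gaussian mixed model with fixed temperature,
#' pCO2 and temperature x pCO2 effects and scalar random effects of genotype
#' and tank, then computes broad-sense heritability draw-wise as
#'
#' \deqn{H^2 = V_{genotype} / (V_{genotype} + V_{tank} + V_{residual}),}
#'
#' the genotype share of the summed random-factor variance. Summaries (mean,
#' 2.5/50/97.5% quantiles) are taken over the retained draws of \eqn{H^2}
#' itself, not as a ratio of summaries.
#'
#' @param table A trait table.
#' @param trait Trait to fit.
#' @param config A [chain_config()].
#' @param scope `"all_treatments"` (default): one model across the full
#'   factorial with the treatment fixed effects; `"per_treatment"`: refit on
#'   each treatment subset with an intercept-only mean (returns a named list
#'   of decompositions).
#' @return An object of class `variance_decomposition`: `draws` (data.frame
#'   of retained `V_genotype`, `V_tank`, `V_residual`, `h2` draws, stacked
#'   across chains), `summary` (mean and quantiles of `h2`), `diagnostics`
#'   (effective sample size and split-chain R-hat for `h2`), plus the config.
#'   For `scope = "per_treatment"`, a named list of such objects.
#' @export
fit_heritability <- function(table, trait, config = chain_config(),
                             scope = c("all_treatments", "per_treatment")) {
  scope <- match.arg(scope)
  stopifnot(inherits(config, "chain_config"))
  table <- validate_trait_table(table)
  d <- .trait_subset(table, trait)

  if (scope == "per_treatment") {
    out <- lapply(seq_along(levels(d$treatment)), function(i) {
      trt <- levels(d$treatment)[i]
      sub <- table[table$trait_name == trait & table$treatment == trt, ]
      cfg <- config
      cfg$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
      .fit_h2_one(sub, trait, cfg, intercept_only = TRUE)
    })
    names(out) <- levels(d$treatment)
    return(out)
  }
  .fit_h2_one(d, trait, config, intercept_only = FALSE)
}

.fit_h2_one <- function(d, trait, config, intercept_only = FALSE) {
  d <- .trait_subset(as.data.frame(d), trait)
  y <- d$value
  if (intercept_only) {
    X <- matrix(1, length(y), 1)
  } else {
    # two-stressor factorial coding: temperature, pCO2, interaction
    temp <- as.integer(d$treatment %in% c("high_temp", "combined"))
    pco2 <- as.integer(d$treatment %in% c("high_pco2", "combined"))
    X <- stats::model.matrix(~ temp * pco2)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: fixed-effect matrix is rank deficient for ",
         "trait '", trait, "'")
  }
  gidx <- as.integer(droplevels(d$genotype_id)) - 1L
  tidx <- as.integer(droplevels(d$tank_id)) - 1L

  chains <- lapply(seq_len(config$n_chains), function(ch) {
    .run_chain(y, X, gidx, tidx, config,
               seed = (config$seed + 104729L * (ch - 1L)) %% .Machine$integer.max)
  })
  draws <- do.call(rbind, chains)
  h2 <- draws[, "V_genotype"] /
    (draws[, "V_genotype"] + draws[, "V_tank"] + draws[, "V_residual"])
  draws <- data.frame(draws, h2 = h2)

  per_chain_h2 <- lapply(chains, function(m) {
    m[, "V_genotype"] / (m[, "V_genotype"] + m[, "V_tank"] + m[, "V_residual"])
  })

  qs <- stats::quantile(h2, c(0.025, 0.5, 0.975), names = FALSE)
  structure(
    list(trait = trait,
         draws = draws,
         summary = c(mean = mean(h2), q2.5 = qs[1], median = qs[2],
                     q97.5 = qs[3]),
         diagnostics = c(ess = effective_sample_size(h2),
                         rhat = split_rhat(per_chain_h2)),
         config = config),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  s <- x$summary
  cat("Broad-sense heritability of '", x$trait, "'\n", sep = "")
  cat(sprintf("  H2 = %.3f (95%% CrI %.3f-%.3f, median %.3f)\n",
              s["mean"], s["q2.5"], s["q97.5"], s["median"]))
  cat(sprintf("  %d retained draws, ESS %.0f, split R-hat %.3f\n",
              nrow(x$draws), x$diagnostics["ess"], x$diagnostics["rhat"]))
  invisible(x)
}

#' Summarize heritability across traits
#'
#' @param decomps Named list (trait -> `variance_decomposition`), e.g. from
#'   fitting each trait of a table.
#' @return A data.frame with one row per trait — mean H2, 95% interval,
#'   median, effective sample size — sorted by decreasing mean H2.
#' @export
h2_report <- function(decomps) {
  stopifnot(length(decomps) >= 1)
  rows <- lapply(decomps, function(dc) {
    s <- dc$summary
    data.frame(trait = dc$trait, mean_h2 = unname(s["mean"]),
               q2.5 = unname(s["q2.5"]), median = unname(s["median"]),
               q97.5 = unname(s["q97.5"]),
               ess = unname(dc$diagnostics["ess"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_h2), ]
  rownames(out) <- NULL
  out
}
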
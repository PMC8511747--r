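# Independent oracles used by the test suite. These deliberately take
# different computational routes from the package implementation.

# Method-of-moments (ANOVA) variance components on a balanced design:
# tank mean square after the fixed effects, against the residual mean square.
mom_varcomp <- function(d) {
  fit <- stats::lm(value ~ treatment * genotype_id + tank_id, data = d)
  a <- stats::anova(fit)
  ms_res <- a["Residuals", "Mean Sq"]
  ms_tank <- a["tank_id", "Mean Sq"]
  m <- mean(table(d$tank_id))
  list(V_residual = ms_res, V_tank = (ms_tank - ms_res) / m)
}

# Upper-tail studentized range probability by direct double quadrature:
# condition on the scale chi variate, integrate the range CDF over z.
ptukey_oracle <- function(q, k, df) {
  range_cdf <- function(qu) {
    stats::integrate(function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - qu))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  dchi_scaled <- function(u) {
    # density of sqrt(chisq_df / df)
    exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(u) -
          df * u^2 / 2) * 2
  }
  cdf <- stats::integrate(function(u) {
    vapply(u, function(ui) dchi_scaled(ui) * range_cdf(q * ui), 0)
  }, 0, Inf, rel.tol = 1e-9)$value
  1 - cdf
}

# All permutations of a vector (small n only)
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub, deparse.level = 0))
  }
  out
}

# Exhaustive-relabelling PERMANOVA p for two equal groups of size n/2
permanova_exhaustive_p <- function(X, groups) {
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  fstat <- function(g) {
    ssw <- 0
    for (l in lev) {
      idx <- which(g == l)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- fstat(groups)
  n_a <- sum(groups == lev[1])
  sel <- utils::combn(n, n_a)
  fs <- apply(sel, 2, function(idx) {
    g <- rep(lev[2], n); g[idx] <- lev[1]
    fstat(g)
  })
  mean(fs >= f_obs - 1e-12)
}

# Exhaustive permutation p for a Pearson correlation (n <= 7)
pearson_perm_p <- function(x, y) {
  r_obs <- stats::cor(x, y)
  P <- all_perms(seq_along(y))
  rs <- apply(P, 1, function(idx) stats::cor(x, y[idx]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Noiseless default-structure design with selected traits
noiseless_design <- function(traits, seed = 1) {
  design_spec(traits = traits, seed = seed)
}

zero_noise <- function(spec) {
  spec$V_genotype <- 0; spec$V_tank <- 0; spec$V_residual <- 0
  spec
}

# single-trait design helper used across tests
one_trait_design <- function(..., n_genotypes = 12, n_tanks_per_treatment = 5,
                             seed = 1) {
  design_spec(n_genotypes = n_genotypes,
              n_tanks_per_treatment = n_tanks_per_treatment,
              traits = list(trait_spec(...)), seed = seed)
}
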
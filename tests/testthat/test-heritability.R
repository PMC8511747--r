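fast_chain <- function(seed = 1, n_chains = 1) {
  chain_config(n_iterations = 6000, burn_in = 1000, thin = 5, seed = seed,
               n_chains = n_chains)
}

# rho_G = 1 by default: the scalar-genotype heritability model assumes one
# genotype effect shared across treatments, which is the generative case of
# fully correlated genotype effects
h2_design <- function(h2, seed, n_genotypes = 12, n_tanks = 5, v_tot = 1,
                      rho_G = 1) {
  one_trait_design("y", control_mean = 10, delta_temp = -0.2,
                   delta_pco2 = -0.1, V_genotype = h2 * v_tot,
                   V_tank = 0.1 * v_tot,
                   V_residual = if (h2 < 0.9) (0.9 - h2) * v_tot else 0.1,
                   rho_G = rho_G,
                   n_genotypes = n_genotypes,
                   n_tanks_per_treatment = n_tanks, seed = seed)
}

test_that("chain bookkeeping retains floor((iter - burn)/thin) draws", {
  expect_equal(retained_draws(chain_config()), 2000)
  expect_equal(retained_draws(chain_config(10000, 1000, 7)), 1285)
  expect_error(chain_config(1000, 2000, 10))
  tab <- simulate_experiment(h2_design(0.4, seed = 41))
  dec <- fit_heritability(tab, "y", fast_chain())
  expect_equal(nrow(dec$draws), 1000)
})

test_that("H2 draws are the exact per-draw variance ratio, inside [0,1]", {
  tab <- simulate_experiment(h2_design(0.3, seed = 43))
  dec <- fit_heritability(tab, "y", fast_chain(seed = 2))
  with(dec$draws, {
    expect_equal(h2, V_genotype / (V_genotype + V_tank + V_residual))
    expect_true(all(h2 >= 0 & h2 <= 1))
  })
})

test_that("chains are bit-reproducible by seed; seeds agree within MC error", {
  tab <- simulate_experiment(h2_design(0.4, seed = 47))
  a <- fit_heritability(tab, "y", fast_chain(seed = 5))
  b <- fit_heritability(tab, "y", fast_chain(seed = 5))
  expect_identical(a$draws, b$draws)

  c3 <- fit_heritability(tab, "y", fast_chain(seed = 6))
  mcse <- sd(a$draws$h2) / sqrt(a$diagnostics[["ess"]])
  expect_lt(abs(mean(a$draws$h2) - mean(c3$draws$h2)), 3 * 2 * mcse)
})

test_that("no genetic variance concentrates the posterior near zero", {
  tab <- simulate_experiment(h2_design(0, seed = 53))
  dec <- fit_heritability(tab, "y", fast_chain(seed = 7))
  expect_lt(dec$summary[["median"]], 0.10)
  expect_lt(dec$summary[["q97.5"]], 0.30)
})

test_that("posterior H2 is invariant to shifting and scaling the trait", {
  tab <- simulate_experiment(h2_design(0.4, seed = 59))
  base <- fit_heritability(tab, "y", fast_chain(seed = 8))
  shifted <- tab; shifted$value <- shifted$value + 100
  scaled <- tab; scaled$value <- scaled$value * 37
  m_base <- mean(base$draws$h2)
  tol <- 8 * sd(base$draws$h2) / sqrt(base$diagnostics[["ess"]])
  expect_lt(abs(mean(fit_heritability(shifted, "y",
                                      fast_chain(seed = 8))$draws$h2) - m_base),
            tol)
  expect_lt(abs(mean(fit_heritability(scaled, "y",
                                      fast_chain(seed = 8))$draws$h2) - m_base),
            tol)
})

test_that("fixed-effect draws match the closed-form conjugate posterior", {
  # pin the random-effect variances near zero and the residual variance at a
  # known value: the fixed effects then have the analytic normal posterior
  # beta | y ~ N(beta_ols, sigma2 (X'X)^-1)
  set.seed(61)
  n <- 80
  trt <- rep(treatment_levels(), each = n / 4)
  temp <- as.integer(trt %in% c("high_temp", "combined"))
  pco2 <- as.integer(trt %in% c("high_pco2", "combined"))
  X <- stats::model.matrix(~ temp * pco2)
  sigma2 <- 0.49
  y <- X %*% c(5, -1, -0.5, -0.8) + rnorm(n, sd = sqrt(sigma2))
  gidx <- rep(0:9, length.out = n)
  tidx <- rep(0:7, length.out = n)

  pin <- 1e9
  set.seed(62)
  draws <- coralqg:::gibbs_varcomp(
    as.vector(y), X, as.integer(gidx), as.integer(tidx),
    n_iter = 22000, burn_in = 2000, thin = 2,
    prior_shape = c(pin, pin, pin),
    prior_rate = c(pin * 1e-10, pin * 1e-10, pin * sigma2))

  beta_draws <- draws[, 4:7]
  beta_ols <- solve(crossprod(X), crossprod(X, y))
  cov_beta <- sigma2 * solve(crossprod(X))
  for (j in 1:4) {
    expect_equal(mean(beta_draws[, j]), beta_ols[j],
                 tolerance = 5 * sqrt(cov_beta[j, j] / 1000))
    expect_equal(sd(beta_draws[, j]), sqrt(cov_beta[j, j]), tolerance = 0.08)
  }
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  tab <- simulate_experiment(h2_design(0.4, seed = 67))
  dec <- fit_heritability(tab, "y", chain_config(12000, 2000, 5, seed = 9))

  d <- tab[tab$trait_name == "y", ]
  temp <- as.integer(d$treatment %in% c("high_temp", "combined"))
  pco2 <- as.integer(d$treatment %in% c("high_pco2", "combined"))
  model <- "
    model {
      for (i in 1:n) {
        mu[i] <- b0 + b1*temp[i] + b2*pco2[i] + b3*temp[i]*pco2[i] +
                 g[gen[i]] + t[tank[i]]
        y[i] ~ dnorm(mu[i], 1/s2e)
      }
      for (j in 1:ng) { g[j] ~ dnorm(0, 1/s2g) }
      for (k in 1:nt) { t[k] ~ dnorm(0, 1/s2t) }
      b0 ~ dnorm(0, 1e-8); b1 ~ dnorm(0, 1e-8)
      b2 ~ dnorm(0, 1e-8); b3 ~ dnorm(0, 1e-8)
      s2e <- 1/ig_e; ig_e ~ dgamma(0.001, 0.001)
      s2g <- 1/ig_g; ig_g ~ dgamma(0.001, 0.001)
      s2t <- 1/ig_t; ig_t ~ dgamma(0.001, 0.001)
    }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(y = d$value, n = nrow(d), temp = temp, pco2 = pco2,
                gen = as.integer(factor(d$genotype_id)),
                tank = as.integer(factor(d$tank_id)),
                ng = length(unique(d$genotype_id)),
                nt = length(unique(d$tank_id))),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 10),
    n.chains = 1, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  samp <- rjags::jags.samples(jm, c("s2g", "s2t", "s2e"), n.iter = 10000,
                              thin = 5, progress.bar = "none")
  h2_jags <- as.vector(samp$s2g) /
    (as.vector(samp$s2g) + as.vector(samp$s2t) + as.vector(samp$s2e))
  expect_lt(abs(mean(dec$draws$h2) - mean(h2_jags)), 0.03)
  expect_lt(abs(unname(quantile(dec$draws$h2, 0.5)) - median(h2_jags)), 0.03)
})

test_that("per-treatment scope refits each subset with an intercept model", {
  tab <- simulate_experiment(h2_design(0.4, seed = 71))
  by_trt <- fit_heritability(tab, "y", fast_chain(seed = 11),
                             scope = "per_treatment")
  expect_named(by_trt, treatment_levels())
  for (dec in by_trt) {
    expect_equal(nrow(dec$draws), 1000)
    expect_true(all(dec$draws$h2 >= 0 & dec$draws$h2 <= 1))
  }
})

test_that("estimates track ground truth on an enlarged design", {
  tab <- simulate_experiment(h2_design(0.5, seed = 73, n_genotypes = 40,
                                       n_tanks = 8))
  dec <- fit_heritability(tab, "y", fast_chain(seed = 12))
  expect_lt(abs(dec$summary[["mean"]] - 0.5), 0.10)
  expect_true(dec$summary[["q2.5"]] < 0.5 & 0.5 < dec$summary[["q97.5"]])
})

test_that("the report summarizes and sorts traits deterministically", {
  tab <- simulate_experiment(design_spec(
    traits = list(trait_spec("hi", 10, V_genotype = 0.6, V_tank = 0.1,
                             V_residual = 0.3),
                  trait_spec("lo", 10, V_genotype = 0.05, V_tank = 0.1,
                             V_residual = 0.85)),
    seed = 79))
  decs <- list(hi = fit_heritability(tab, "hi", fast_chain(seed = 13)),
               lo = fit_heritability(tab, "lo", fast_chain(seed = 14)))
  rep1 <- h2_report(decs)
  expect_equal(rep1$trait, c("hi", "lo"))  # sorted by decreasing mean H2
  expect_equal(rep1$mean_h2[1], mean(decs$hi$draws$h2))

  # identical data and seed give identical summaries
  dec2 <- fit_heritability(tab, "hi", fast_chain(seed = 13))
  expect_identical(decs$hi$summary, dec2$summary)
})
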
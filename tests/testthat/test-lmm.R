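sim_one_trait <- function(V_tank, V_residual, V_genotype = 0.3, seed = 1,
                          n_genotypes = 12, n_tanks = 5) {
  d <- one_trait_design("y", control_mean = 10, delta_temp = -0.2,
                        delta_pco2 = -0.1, V_genotype = V_genotype,
                        V_tank = V_tank, V_residual = V_residual,
                        n_genotypes = n_genotypes,
                        n_tanks_per_treatment = n_tanks, seed = seed)
  simulate_experiment(d)
}

test_that("REML matches balanced-design method-of-moments when interior", {
  tab <- sim_one_trait(V_tank = 0.4, V_residual = 0.5, seed = 3)
  fit <- fit_trait_lmm(tab, "y")
  mom <- mom_varcomp(fit$data)
  expect_gt(fit$V_tank, 0)  # interior
  expect_equal(fit$V_tank, mom$V_tank, tolerance = 1e-6)
  expect_equal(fit$V_residual, mom$V_residual, tolerance = 1e-6)
})

test_that("REML agrees with lme4 on variance components and logLik", {
  skip_if_not_installed("lme4")
  tab <- sim_one_trait(V_tank = 0.2, V_residual = 0.6, seed = 5)
  fit <- fit_trait_lmm(tab, "y")
  # same sum-to-zero basis: the REML log-likelihood depends on the
  # fixed-effect parameterization
  ref <- lme4::lmer(value ~ treatment * genotype_id + (1 | tank_id),
                    data = fit$data, REML = TRUE,
                    contrasts = list(treatment = "contr.sum",
                                     genotype_id = "contr.sum"))
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$V_tank, vc$vcov[vc$grp == "tank_id"], tolerance = 1e-5)
  expect_equal(fit$V_residual, vc$vcov[vc$grp == "Residual"], tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-5)
})

test_that("zero tank variance hits the boundary and reduces to OLS", {
  tab <- sim_one_trait(V_tank = 0, V_residual = 0.5, seed = 7,
                       n_genotypes = 8, n_tanks = 20)
  fit <- fit_trait_lmm(tab, "y")
  expect_equal(fit$V_tank, 0)
  ols <- stats::lm(value ~ treatment * genotype_id, data = fit$data,
                   contrasts = list(treatment = "contr.sum",
                                    genotype_id = "contr.sum"))
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-8)
})

test_that("fit is invariant to row order", {
  tab <- sim_one_trait(V_tank = 0.3, V_residual = 0.5, seed = 11)
  fit1 <- fit_trait_lmm(tab, "y")
  set.seed(1)
  fit2 <- fit_trait_lmm(tab[sample(nrow(tab)), ], "y")
  expect_equal(fit2$lambda, fit1$lambda, tolerance = 1e-8)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-8)
})

test_that("containment F-tests reproduce the balanced-design degrees of freedom", {
  tab <- sim_one_trait(V_tank = 0.3, V_residual = 0.5, seed = 13)
  fit <- fit_trait_lmm(tab, "y")
  an <- anova(fit)
  expect_equal(an$df_num, c(3, 11, 33))
  expect_equal(an$df_den[an$term == "treatment"], 16)  # 20 tanks - 4 treatments
  expect_equal(an$df_den[an$term == "genotype"], 240 - 48 - 16)
  expect_true(all(an$p > 0 & an$p <= 1))
})

test_that("treatment F equals the split-plot tank-MS ratio on balanced data", {
  tab <- sim_one_trait(V_tank = 0.4, V_residual = 0.5, seed = 17)
  fit <- fit_trait_lmm(tab, "y")
  an <- anova(fit)
  a <- stats::anova(stats::lm(value ~ treatment * genotype_id + tank_id,
                              data = fit$data))
  f_classic <- a["treatment", "Mean Sq"] / a["tank_id", "Mean Sq"]
  expect_equal(an$F[an$term == "treatment"], f_classic, tolerance = 1e-6)
})

test_that("Satterthwaite df agrees with lmerTest on the treatment test", {
  skip_if_not_installed("lmerTest")
  tab <- sim_one_trait(V_tank = 0.3, V_residual = 0.5, seed = 19)
  fit <- fit_trait_lmm(tab, "y")
  an <- anova(fit, ddf_method = "satterthwaite")
  ref <- lmerTest::lmer(value ~ treatment * genotype_id + (1 | tank_id),
                        data = fit$data)
  ran <- stats::anova(ref, type = 3, ddf = "Satterthwaite")
  expect_equal(an$df_den[an$term == "treatment"], ran["treatment", "DenDF"],
               tolerance = 0.02)
  expect_equal(an$F[an$term == "treatment"], ran["treatment", "F value"],
               tolerance = 1e-4)
})

test_that("variance-component recovery over repeated simulation", {
  vt_hat <- ve_hat <- numeric(60)
  for (i in seq_len(60)) {
    tab <- sim_one_trait(V_tank = 0.4, V_residual = 0.8, seed = 1000 + i)
    f <- fit_trait_lmm(tab, "y")
    vt_hat[i] <- f$V_tank
    ve_hat[i] <- f$V_residual
  }
  expect_equal(median(vt_hat), 0.4, tolerance = 0.10)
  expect_equal(median(ve_hat), 0.8, tolerance = 0.05)
})

test_that("empty genotype-by-treatment cells are named in the error", {
  tab <- sim_one_trait(V_tank = 0.2, V_residual = 0.5, seed = 23)
  drop <- !(tab$genotype_id == "G03" & tab$treatment == "high_pco2")
  expect_error(fit_trait_lmm(tab[drop, ], "y"), "G03.*high_pco2")
})

test_that("Tukey HSD matches direct studentized-range integration", {
  tab <- sim_one_trait(V_tank = 0.3, V_residual = 0.5, seed = 29)
  fit <- fit_trait_lmm(tab, "y")
  hsd <- tukey_hsd(fit)
  expect_equal(nrow(hsd), 6)
  for (j in c(1, 4, 6)) {
    q <- abs(hsd$estimate[j]) / (hsd$se[j] / sqrt(2))
    expect_equal(hsd$p_adjusted[j], ptukey_oracle(q, k = 4, df = 16),
                 tolerance = 1e-6)
  }
})

test_that("Tukey p is 1 for identical means and never below the t-test p", {
  # copy the high_temp response pattern into high_pco2 so the two treatment
  # sample means are exactly equal while residual noise remains
  tab <- sim_one_trait(V_tank = 0.2, V_residual = 0.5, seed = 31)
  tab <- tab[order(tab$treatment, tab$genotype_id, tab$tank_id), ]
  tab$value[tab$treatment == "high_pco2"] <-
    tab$value[tab$treatment == "high_temp"]
  fit <- fit_trait_lmm(tab, "y")
  hsd <- tukey_hsd(fit)
  row <- hsd$level_a == "high_temp" & hsd$level_b == "high_pco2"
  expect_equal(hsd$estimate[row], 0, tolerance = 1e-12)
  expect_gt(hsd$p_adjusted[row], 0.999999)

  tab2 <- sim_one_trait(V_tank = 0.3, V_residual = 0.5, seed = 37)
  fit2 <- fit_trait_lmm(tab2, "y")
  hsd2 <- tukey_hsd(fit2)
  p_t <- 2 * stats::pt(abs(hsd2$estimate) / hsd2$se, df = 16,
                       lower.tail = FALSE)
  expect_true(all(hsd2$p_adjusted >= p_t - 1e-12))
})
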
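#' Simulate a trait table from a factorial design
#'
#' Generates fragment-level phenotype values with the additive structure
#'
#' \deqn{y = \mu_c (1 + \Delta_{trt}) + g_{genotype,trt} + t_{tank} + e}
#'
#' where the genotype effects of one genet are drawn jointly across the four
#' treatments from a multivariate normal with variance `V_genotype` and
#' exchangeable cross-treatment correlation `rho_G`, tank effects are
#' `N(0, V_tank)` per tank, and residuals are `N(0, V_residual)` per
#' fragment. For the combined treatment \eqn{\Delta} is the additive null
#' `delta_temp + delta_pco2` shifted by the trait's interaction mode (see
#' [delta_combined()]). Values below `value_floor` are clipped and counted.
#'
#' @param design A [design_spec()].
#' @param seed Optional integer overriding `design$seed`.
#'
#' @return A long-format `data.frame` with columns `fragment_id`,
#'   `genotype_id`, `treatment`, `tank_id`, `trait_name`, `value` — one row
#'   per fragment x trait. Attributes: `design` (the generating spec),
#'   `ground_truth` (per-trait data.frame of generative deltas, variance
#'   components and heritability), `n_clipped` (named count of floor-clipped
#'   values per trait), `n_dropped` (fragments removed by dropout).
#' @examples
#' tab <- simulate_experiment(design_spec(seed = 1))
#' nrow(tab) / length(design_spec()$traits)  # 240 fragments
#' @export
simulate_experiment <- function(design, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(seed)) seed <- design$seed
  set.seed(as.integer(seed))

  trts <- treatment_levels()
  nG <- design$n_genotypes
  nT <- length(trts)
  nK <- design$n_tanks_per_treatment

  # layout: tanks nested in treatment; one fragment of each genotype per tank
  tank_id <- paste0("tank_", sprintf("%02d", seq_len(nT * nK)))
  tank_trt <- rep(trts, each = nK)
  layout <- do.call(rbind, lapply(seq_along(tank_id), function(k) {
    data.frame(genotype_id = paste0("G", sprintf("%02d", seq_len(nG))),
               treatment = tank_trt[k], tank_id = tank_id[k],
               stringsAsFactors = FALSE)
  }))
  layout$fragment_id <- paste0("frag_", sprintf("%03d", seq_len(nrow(layout))))

  # optional fragment dropout (mortality)
  n_dropped <- 0L
  if (design$dropout_rate > 0) {
    keep <- stats::runif(nrow(layout)) >= design$dropout_rate
    n_dropped <- sum(!keep)
    layout <- layout[keep, , drop = FALSE]
  }

  trt_idx <- match(layout$treatment, trts)
  gen_idx <- match(layout$genotype_id, unique(layout$genotype_id))

  out <- vector("list", length(design$traits))
  n_clipped <- integer(length(design$traits))
  names(n_clipped) <- names(design$traits)

  for (j in seq_along(design$traits)) {
    sp <- design$traits[[j]]
    deltas <- c(0, sp$delta_temp, sp$delta_pco2, delta_combined(sp))
    mu <- sp$control_mean * (1 + deltas)

    # genotype effects: nG independent draws from MVN(0, Sigma),
    # Sigma = V_g * [(1 - rho) I + rho J] over the 4 treatments
    if (sp$V_genotype > 0) {
      Sg <- sp$V_genotype * ((1 - sp$rho_G) * diag(nT) + sp$rho_G)
      ev <- eigen(Sg, symmetric = TRUE)
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nT)
      gmat <- matrix(stats::rnorm(nG * nT), nG, nT) %*% t(A)
    } else {
      gmat <- matrix(0, nG, nT)
    }
    tank_eff <- stats::rnorm(nT * nK, 0, sqrt(sp$V_tank))
    names(tank_eff) <- tank_id

    value <- mu[trt_idx] +
      gmat[cbind(gen_idx, trt_idx)] +
      tank_eff[layout$tank_id] +
      stats::rnorm(nrow(layout), 0, sqrt(sp$V_residual))

    if (!is.null(sp$value_floor)) {
      below <- value < sp$value_floor
      n_clipped[j] <- sum(below)
      value[below] <- sp$value_floor
    }

    out[[j]] <- data.frame(layout[c("fragment_id", "genotype_id",
                                    "treatment", "tank_id")],
                           trait_name = sp$name, value = value,
                           stringsAsFactors = FALSE)
  }

  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  total_clipped <- sum(n_clipped)
  if (total_clipped > 0) {
    message("simulate_experiment: clipped ", total_clipped,
            " value(s) at trait floors")
  }

  gt <- do.call(rbind, lapply(design$traits, function(sp) {
    data.frame(trait_name = sp$name, control_mean = sp$control_mean,
               delta_temp = sp$delta_temp, delta_pco2 = sp$delta_pco2,
               delta_combined = delta_combined(sp),
               additive_null = sp$delta_temp + sp$delta_pco2,
               interaction_mode = sp$interaction_mode,
               V_genotype = sp$V_genotype, V_tank = sp$V_tank,
               V_residual = sp$V_residual, rho_G = sp$rho_G,
               h2 = if (sp$V_genotype + sp$V_tank + sp$V_residual > 0)
                 ground_truth_h2(sp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(gt) <- NULL

  structure(tab, design = design, ground_truth = gt,
            n_clipped = n_clipped, n_dropped = n_dropped)
}

#' Ground truth of a simulated trait table
#'
#' @param table A table produced by [simulate_experiment()].
#' @return The per-trait data.frame of generative parameters attached by the
#'   generator (deltas, interaction mode, variance components, heritability).
#' @export
ground_truth <- function(table) {
  gt <- attr(table, "ground_truth")
  if (is.null(gt)) stop("table carries no ground-truth attribute; ",
                        "was it produced by simulate_experiment()?")
  gt
}
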
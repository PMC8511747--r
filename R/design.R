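#' Treatment levels of the factorial stress design
#'
#' The four treatment conditions of the two-stressor factorial: ambient
#' control, elevated temperature, elevated pCO2, and both stressors combined.
#'
#' @return Character vector of the four treatment labels, in canonical order.
#' @export
treatment_levels <- function() {
  c("control", "high_temp", "high_pco2", "combined")
}

#' Specify one simulated phenotype trait
#'
#' A `trait_spec` holds the generative parameters for one phenotype: the
#' control-condition mean, per-stressor relative effects, the interaction mode
#' of the combined treatment, and the variance components that define the
#' trait's broad-sense heritability.
#'
#' @param name Trait label.
#' @param control_mean Mean value under control conditions (trait units).
#' @param delta_temp,delta_pco2 Relative effect of each single stressor versus
#'   control (dimensionless; `-0.3` means a 30% decline).
#' @param interaction_mode One of `"additive"`, `"synergistic"`,
#'   `"antagonistic"`. Under the additive mode the combined-treatment relative
#'   effect is exactly `delta_temp + delta_pco2`; the synergistic mode pushes
#'   it `interaction_magnitude` further from zero in the direction of the
#'   additive null, the antagonistic mode pulls it back towards zero.
#' @param interaction_magnitude Non-negative offset applied to the combined
#'   treatment's relative effect (on the relative-difference scale).
#' @param V_genotype,V_tank,V_residual Variance components (trait units
#'   squared) for genotype identity, shared tank environment, and residual
#'   fragment-level noise.
#' @param rho_G Cross-treatment genetic correlation in `[-1, 1]`: the
#'   correlation of a genotype's random effect between any two treatments.
#'   Positive values emulate broad-spectrum resistance (genets good under one
#'   stressor are good under another); negative values emulate tradeoffs.
#' @param value_floor Optional lower bound for simulated values (e.g. 0 for
#'   concentrations); clipped values are counted and reported.
#'
#' @return An object of class `trait_spec`.
#' @seealso [design_spec()], [ground_truth_h2()]
#' @export
trait_spec <- function(name, control_mean,
                       delta_temp = 0, delta_pco2 = 0,
                       interaction_mode = c("additive", "synergistic", "antagonistic"),
                       interaction_magnitude = 0,
                       V_genotype = 0, V_tank = 0, V_residual = 0,
                       rho_G = 0, value_floor = NULL) {
  interaction_mode <- match.arg(interaction_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (any(c(V_genotype, V_tank, V_residual) < 0)) {
    stop("variance components must be non-negative (trait '", name, "')")
  }
  if (interaction_magnitude < 0) {
    stop("interaction_magnitude must be non-negative (trait '", name, "')")
  }
  if (abs(rho_G) > 1) {
    stop("rho_G must lie in [-1, 1] (trait '", name, "')")
  }
  # exchangeable 4x4 correlation is PSD iff rho >= -1/(k-1) = -1/3
  if (rho_G < -1 / 3 && V_genotype > 0) {
    stop("rho_G = ", rho_G, " makes the exchangeable 4-treatment genetic ",
         "covariance non-positive-semi-definite (requires rho_G >= -1/3)")
  }
  structure(
    list(name = name, control_mean = control_mean,
         delta_temp = delta_temp, delta_pco2 = delta_pco2,
         interaction_mode = interaction_mode,
         interaction_magnitude = interaction_magnitude,
         V_genotype = V_genotype, V_tank = V_tank, V_residual = V_residual,
         rho_G = rho_G, value_floor = value_floor),
    class = "trait_spec"
  )
}

#' Combined-treatment relative effect implied by a trait specification
#'
#' @param spec A [trait_spec()].
#' @return The generative relative effect of the combined treatment:
#'   `delta_temp + delta_pco2` for the additive mode, shifted by
#'   `interaction_magnitude` away from zero (synergistic) or towards zero
#'   (antagonistic). The shift direction follows the sign of the additive
#'   null; a zero null is treated as a decline.
#' @export
delta_combined <- function(spec) {
  null <- spec$delta_temp + spec$delta_pco2
  s <- if (null == 0) -1 else sign(null)
  switch(spec$interaction_mode,
         additive     = null,
         synergistic  = null + s * spec$interaction_magnitude,
         antagonistic = null - s * spec$interaction_magnitude)
}

#' Ground-truth broad-sense heritability of a trait specification
#'
#' Broad-sense heritability is the genotype share of the total random
#' variance: `V_genotype / (V_genotype + V_tank + V_residual)`.
#'
#' @param spec A [trait_spec()].
#' @return The heritability implied by the generative variance components.
#' @examples
#' ground_truth_h2(trait_spec("x", 1, V_genotype = 4, V_tank = 2, V_residual = 2))
#' @export
ground_truth_h2 <- function(spec) {
  tot <- spec$V_genotype + spec$V_tank + spec$V_residual
  if (tot <= 0) {
    stop("heritability undefined: all variance components are zero")
  }
  spec$V_genotype / tot
}

#' Default trait panel for the simulated experiment
#'
#' Twelve phenotypes spanning holobiont growth, host biomass and immunity, and
#' symbiont photophysiology, parameterized to reflect the qualitative pattern
#' typical of combined warming/acidification exposures: synergistic declines
#' in cumulative holobiont measures (growth, symbiont density, chlorophyll,
#' host protein, ETRm), antagonism in endpoint calcification and immune
#' enzymes, a near-additive decline in photochemical yield, and opposing
#' single-stressor effects on the P:R ratio. Immune enzymes and buoyant-weight
#' growth carry high heritability (~0.57); the remaining traits ~0.1-0.2.
#'
#' @param sd_frac Total random standard deviation as a fraction of the control
#'   mean (default 0.15).
#' @param rho_G Cross-treatment genetic correlation shared by all traits
#'   (default 0.5, i.e. broad-spectrum resistance).
#' @return A named list of [trait_spec()] objects.
#' @export
default_traits <- function(sd_frac = 0.15, rho_G = 0.5) {
  mk <- function(name, mean, dt, dp, mode, mag, h2, floor = 0) {
    v_tot <- (sd_frac * mean)^2
    tank_frac <- 0.10
    trait_spec(name, mean,
               delta_temp = dt, delta_pco2 = dp,
               interaction_mode = mode, interaction_magnitude = mag,
               V_genotype = h2 * v_tot,
               V_tank = tank_frac * v_tot,
               V_residual = (1 - h2 - tank_frac) * v_tot,
               rho_G = rho_G, value_floor = floor)
  }
  specs <- list(
    mk("buoyant_weight",      0.80, -0.15, -0.10, "synergistic",  0.25, 0.57),
    mk("calcification_light", 0.60, -0.55, -0.55, "antagonistic", 0.45, 0.15),
    mk("calcification_dark",  0.40, -0.55, -0.50, "antagonistic", 0.40, 0.10),
    mk("symbiont_density",    1.50, -0.35, -0.05, "synergistic",  0.35, 0.20),
    mk("chl_total",           3.00, -0.40,  0.00, "synergistic",  0.35, 0.20),
    mk("protein_host",        1.20, -0.25, -0.05, "synergistic",  0.20, 0.20),
    mk("ppo",                 0.50, -0.20, -0.15, "antagonistic", 0.30, 0.57),
    mk("po",                  0.40, -0.20, -0.15, "antagonistic", 0.30, 0.57),
    mk("pox",                 0.30, -0.20, -0.10, "antagonistic", 0.25, 0.57),
    mk("yield",               0.60, -0.25, -0.20, "additive",     0.00, 0.20),
    mk("etrm",               12.00, -0.40, -0.30, "synergistic",  0.10, 0.20),
    mk("pr_ratio",            1.20, -0.20,  0.10, "antagonistic", 0.05, 0.10)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Specify the factorial experimental design
#'
#' Describes the layout of the tank experiment: clonal genotypes crossed with
#' the four treatments, tanks nested in treatments, and one clone-mate of each
#' genotype per tank. The defaults reproduce a 12-genotype design with 5 tank
#' replicates per treatment (20 tanks, 240 fragments).
#'
#' @param n_genotypes Number of clonal genotypes (default 12).
#' @param n_tanks_per_treatment Replicate tanks per treatment (default 5).
#' @param traits List of [trait_spec()] objects (default [default_traits()]).
#' @param dropout_rate Probability that a fragment dies and is dropped from
#'   the table (default 0; the real experiment lost 2 of 240).
#' @param seed Integer seed used by [simulate_experiment()].
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_genotypes = 12, n_tanks_per_treatment = 5,
                        traits = default_traits(), dropout_rate = 0,
                        seed = 1L) {
  stopifnot(n_genotypes >= 2, n_tanks_per_treatment >= 2,
            dropout_rate >= 0, dropout_rate < 1, length(traits) >= 1)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  ok <- vapply(traits, inherits, TRUE, "trait_spec")
  if (!all(ok)) stop("`traits` must be a list of trait_spec objects")
  names(traits) <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(names(traits))) stop("duplicate trait names in design")
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         n_treatments = 4L,
         n_tanks_per_treatment = as.integer(n_tanks_per_treatment),
         n_fragments_per_tank = as.integer(n_genotypes),
         traits = traits, dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Factorial coral stress design\n")
  cat("  genotypes:            ", x$n_genotypes, "\n")
  cat("  treatments:           ", paste(treatment_levels(), collapse = ", "), "\n")
  cat("  tanks per treatment:  ", x$n_tanks_per_treatment, "\n")
  cat("  fragments per tank:   ", x$n_fragments_per_tank, "(one per genotype)\n")
  cat("  total fragments:      ",
      x$n_genotypes * x$n_treatments * x$n_tanks_per_treatment, "\n")
  cat("  traits:               ", length(x$traits), "\n")
  invisible(x)
}
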
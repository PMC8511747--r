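#' Write a design specification to YAML
#'
#' @param design A [design_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_design_spec <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  lst <- list(
    n_genotypes = design$n_genotypes,
    n_tanks_per_treatment = design$n_tanks_per_treatment,
    dropout_rate = design$dropout_rate,
    seed = design$seed,
    traits = lapply(design$traits, function(sp) {
      out <- unclass(sp)
      if (is.null(out$value_floor)) out$value_floor <- NULL
      out
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a design specification from YAML
#'
#' @param path YAML file written by [write_design_spec()] (or hand-authored
#'   with the same fields).
#' @return A [design_spec()].
#' @export
read_design_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  traits <- lapply(lst$traits, function(sp) {
    trait_spec(name = sp$name, control_mean = sp$control_mean,
               delta_temp = sp$delta_temp %||% 0,
               delta_pco2 = sp$delta_pco2 %||% 0,
               interaction_mode = sp$interaction_mode %||% "additive",
               interaction_magnitude = sp$interaction_magnitude %||% 0,
               V_genotype = sp$V_genotype %||% 0,
               V_tank = sp$V_tank %||% 0,
               V_residual = sp$V_residual %||% 0,
               rho_G = sp$rho_G %||% 0,
               value_floor = sp$value_floor)
  })
  design_spec(n_genotypes = lst$n_genotypes %||% 12,
              n_tanks_per_treatment = lst$n_tanks_per_treatment %||% 5,
              traits = traits,
              dropout_rate = lst$dropout_rate %||% 0,
              seed = lst$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
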
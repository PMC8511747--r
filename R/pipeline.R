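#' Configure the end-to-end analysis pipeline
#'
#' Exactly one of `input` (a CSV path or a trait table) or `design` (a
#' [design_spec()], simulated on the fly) must be supplied. All per-stage
#' seeds are derived deterministically from the global `seed`, so a pipeline
#' run is fully reproducible from its configuration.
#'
#' @param input CSV path or trait-table data.frame, or `NULL`.
#' @param design A [design_spec()], or `NULL`.
#' @param unit Analysis unit for the PERMANOVA profile matrix.
#' @param metric Distance metric for the PERMANOVA stage.
#' @param n_permutations Permutations for the PERMANOVA stage.
#' @param chain A [chain_config()] for the heritability stage (its seed is
#'   overridden by the derived stage seed).
#' @param n_boot Bootstrap resamples for the interaction stage.
#' @param alpha Significance level for the tradeoff stage.
#' @param ddf_method Denominator-df method for the mixed-model stage.
#' @param seed Global integer seed.
#' @param out_dir Output directory for per-stage JSON files, or `NULL` to
#'   skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, design = NULL,
                            unit = c("genotype_by_treatment", "fragment"),
                            metric = c("euclidean", "bray_curtis"),
                            n_permutations = 999,
                            chain = chain_config(),
                            n_boot = 2000, alpha = 0.05,
                            ddf_method = c("containment", "satterthwaite"),
                            seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(design)) {
    stop("supply exactly one of `input` (table/CSV) or `design` (simulate)")
  }
  if (!is.null(design)) stopifnot(inherits(design, "design_spec"))
  structure(list(input = input, design = design,
                 unit = match.arg(unit), metric = match.arg(metric),
                 n_permutations = n_permutations, chain = chain,
                 n_boot = n_boot, alpha = alpha,
                 ddf_method = match.arg(ddf_method),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-stage seeds below 2^31
.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483629)
}

.write_stage_json <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Runs, in order: omnibus + pairwise PERMANOVA on the multivariate profile,
#' per-trait mixed models with F-tests and Tukey HSD, Bayesian heritability
#' per trait, additive-null interaction classification, and genotype-mean
#' tradeoff correlations (both modes). Each stage's result is serialized to
#' JSON under `out_dir` when set; a stage failure is recorded in the bundle's
#' error manifest without aborting the remaining stages.
#'
#' @param config A [pipeline_config()].
#' @return A list (class `coral_pipeline`) with elements `table`,
#'   `permanova`, `lmm`, `heritability`, `interactions`, `tradeoffs`, and
#'   `errors` (named list of stage failure messages, empty on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errors <- list()

  table <- if (!is.null(config$design)) {
    simulate_experiment(config$design, seed = .stage_seed(config$seed, 1))
  } else if (is.character(config$input)) {
    read_trait_table(config$input)
  } else {
    validate_trait_table(config$input)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  perm <- run_stage("permanova", {
    X <- profile_matrix(table, unit = config$unit)
    omnibus <- permanova_test(X, attr(X, "groups"),
                              n_permutations = config$n_permutations,
                              seed = .stage_seed(config$seed, 2),
                              metric = config$metric)
    pairwise <- pairwise_permanova(X, attr(X, "groups"),
                                   n_permutations = config$n_permutations,
                                   seed = .stage_seed(config$seed, 3),
                                   metric = config$metric)
    list(omnibus = unclass(omnibus), pairwise = pairwise)
  })

  traits <- trait_names(table)
  lmm <- run_stage("lmm", {
    lapply(stats::setNames(traits, traits), function(tr) {
      fit <- fit_trait_lmm(table, tr, ddf_method = config$ddf_method)
      list(V_tank = fit$V_tank, V_residual = fit$V_residual,
           reml_loglik = fit$reml_loglik,
           anova = anova(fit), posthoc = tukey_hsd(fit))
    })
  })

  herit <- run_stage("heritability", {
    decomps <- lapply(stats::setNames(traits, traits), function(tr) {
      cfg <- config$chain
      cfg$seed <- .stage_seed(config$seed, 4 + match(tr, traits))
      fit_heritability(table, tr, config = cfg)
    })
    list(report = h2_report(decomps),
         retained_draws = vapply(decomps, function(d) nrow(d$draws), 0L),
         diagnostics = t(vapply(decomps, function(d) d$diagnostics,
                                c(ess = 0, rhat = 0))))
  })

  inter <- run_stage("interactions", {
    interaction_table(table, n_boot = config$n_boot,
                      seed = .stage_seed(config$seed, 50))
  })

  trade <- run_stage("tradeoffs", {
    gm <- genotype_means(table)
    list(treatment_by_treatment =
           correlation_report(gm, "treatment_by_treatment",
                              alpha = config$alpha)$entries,
         trait_by_trait =
           correlation_report(gm, "trait_by_trait",
                              alpha = config$alpha)$entries)
  })

  .write_stage_json(perm, config$out_dir, "permanova")
  .write_stage_json(lmm, config$out_dir, "lmm")
  .write_stage_json(herit, config$out_dir, "heritability")
  .write_stage_json(inter, config$out_dir, "interactions")
  .write_stage_json(trade, config$out_dir, "tradeoffs")
  if (length(errors) > 0) .write_stage_json(errors, config$out_dir, "errors")

  structure(list(table = table, permanova = perm, lmm = lmm,
                 heritability = herit, interactions = inter,
                 tradeoffs = trade, errors = errors),
            class = "coral_pipeline")
}

#' @export
print.coral_pipeline <- function(x, ...) {
  cat("Coral multi-stressor analysis bundle\n")
  cat("  fragments x traits rows:", nrow(x$table), "\n")
  if (!is.null(x$permanova)) {
    o <- x$permanova$omnibus
    cat(sprintf("  PERMANOVA: F(%d,%d) = %.2f, R2 = %.3f, p = %.4g\n",
                o$df_between, o$df_within, o$pseudo_F, o$R2, o$p_perm))
  }
  if (!is.null(x$heritability)) {
    top <- x$heritability$report[1, ]
    cat(sprintf("  highest H2: %s = %.2f\n", top$trait, top$mean_h2))
  }
  if (!is.null(x$interactions)) {
    cat("  interaction labels:",
        paste(names(table(x$interactions$label)),
              table(x$interactions$label), collapse = ", "), "\n")
  }
  if (length(x$errors) > 0) {
    cat("  FAILED stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
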
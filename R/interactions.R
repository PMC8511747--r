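#' Relative treatment effects of a trait
#'
#' Relative difference of each stressor treatment versus control,
#' `(mean_trt - mean_control) / mean_control`, with means taken over
#' fragments. This is the scale on which the additive null for the combined
#' treatment is defined.
#'
#' @param table A trait table.
#' @param trait Trait name.
#' @return Named numeric vector `c(delta_temp, delta_pco2, delta_combined)`.
#' @export
relative_effects <- function(table, trait) {
  d <- .trait_subset(validate_trait_table(table), trait)
  mu <- tapply(d$value, d$treatment, mean)
  if (!is.finite(mu[["control"]]) || mu[["control"]] <= 0) {
    stop("control mean must be positive for relative effects (trait '",
         trait, "': control mean = ", mu[["control"]], ")")
  }
  c(delta_temp = (mu[["high_temp"]] - mu[["control"]]) / mu[["control"]],
    delta_pco2 = (mu[["high_pco2"]] - mu[["control"]]) / mu[["control"]],
    delta_combined = (mu[["combined"]] - mu[["control"]]) / mu[["control"]])
}

# deltas from a fragment-level data frame (used by the bootstrap)
.deltas_of <- function(value, treatment) {
  mu <- tapply(value, treatment, mean)
  d <- (mu - mu[["control"]]) / mu[["control"]]
  c(d[["high_temp"]], d[["high_pco2"]], d[["combined"]])
}

#' Classify the combined-stressor response against the additive null
#'
#' The additive null for the combined treatment is the sum of the two
#' single-stressor relative effects; the combined response is called
#' synergistic when it exceeds the null in magnitude (a greater departure
#' from control than the stressors' summed effects), antagonistic when it
#' falls short, and additive otherwise. The default decision rule is a
#' tank-stratified bootstrap: fragments are resampled with replacement
#' within each tank, the magnitude excess `|delta_combined| -
#' |additive_null|` is recomputed per resample, and the call is synergistic
#' (antagonistic) when the 95% percentile interval lies entirely above
#' (below) `tolerance`. `method = "point"` reproduces a plain
#' point-estimate reading of the same rule.
#'
#' Single-stressor effects of opposite sign make the magnitude comparison
#' ambiguous (the null partially cancels); such traits are flagged via
#' `opposing_signs` and a warning rather than force-classified.
#'
#' @param table A trait table.
#' @param trait Trait name.
#' @param tolerance Half-width of the "similar to the line" band on the
#'   magnitude-excess scale (default 0).
#' @param n_boot Bootstrap resamples (default 2000; fewer than 100 warns).
#' @param seed Integer seed for the bootstrap.
#' @param conf Bootstrap interval coverage (default 0.95).
#' @param method `"bootstrap"` (default) or `"point"`.
#' @return An object of class `interaction_report`: trait, the three deltas,
#'   `additive_null`, `deviation` (`delta_combined - additive_null`),
#'   `excess` (`|delta_combined| - |additive_null|`), `ci_deviation`,
#'   `ci_excess`, `label`, `opposing_signs`, `n_boot`, `seed`.
#' @export
classify_interaction <- function(table, trait, tolerance = 0,
                                 n_boot = 2000, seed = 1L, conf = 0.95,
                                 method = c("bootstrap", "point")) {
  method <- match.arg(method)
  d <- .trait_subset(validate_trait_table(table), trait)
  deltas <- relative_effects(d, trait)
  null <- unname(deltas["delta_temp"] + deltas["delta_pco2"])
  dev <- unname(deltas["delta_combined"]) - null
  excess <- abs(unname(deltas["delta_combined"])) - abs(null)

  opposing <- sign(deltas["delta_temp"]) * sign(deltas["delta_pco2"]) < 0
  if (isTRUE(opposing)) {
    warning("single-stressor effects of opposite sign for trait '", trait,
            "'; additive-null magnitude comparison is ambiguous", call. = FALSE)
  }

  ci_dev <- ci_exc <- c(NA_real_, NA_real_)
  tol <- tolerance + 1e-10  # guard against float noise at exact additivity
  if (method == "bootstrap") {
    if (n_boot < 100) warning("n_boot < 100: bootstrap interval unreliable")
    set.seed(as.integer(seed))
    by_tank <- split(seq_len(nrow(d)), d$tank_id)
    boot_exc <- boot_dev <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(by_tank, function(i) i[sample.int(length(i),
                                                             replace = TRUE)]),
                    use.names = FALSE)
      db <- .deltas_of(d$value[idx], d$treatment[idx])
      nb <- db[1] + db[2]
      boot_dev[b] <- db[3] - nb
      boot_exc[b] <- abs(db[3]) - abs(nb)
    }
    a <- (1 - conf) / 2
    ci_dev <- unname(stats::quantile(boot_dev, c(a, 1 - a)))
    ci_exc <- unname(stats::quantile(boot_exc, c(a, 1 - a)))
    label <- if (ci_exc[1] > tol) "synergistic"
             else if (ci_exc[2] < -tol) "antagonistic"
             else "additive"
  } else {
    label <- if (excess > tol) "synergistic"
             else if (excess < -tol) "antagonistic"
             else "additive"
  }

  structure(
    list(trait = trait,
         delta_temp = unname(deltas["delta_temp"]),
         delta_pco2 = unname(deltas["delta_pco2"]),
         delta_combined = unname(deltas["delta_combined"]),
         additive_null = null, deviation = dev, excess = excess,
         ci_deviation = ci_dev, ci_excess = ci_exc,
         label = label, opposing_signs = isTRUE(unname(opposing)),
         tolerance = tolerance, method = method,
         n_boot = if (method == "bootstrap") as.integer(n_boot) else 0L,
         seed = as.integer(seed)),
    class = "interaction_report"
  )
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("Interaction classification for '", x$trait, "': ", x$label, "\n", sep = "")
  cat(sprintf("  deltas: temp %.3f, pCO2 %.3f, combined %.3f (null %.3f)\n",
              x$delta_temp, x$delta_pco2, x$delta_combined, x$additive_null))
  if (x$method == "bootstrap") {
    cat(sprintf("  magnitude excess %.3f (95%% CI %.3f to %.3f, %d resamples)\n",
                x$excess, x$ci_excess[1], x$ci_excess[2], x$n_boot))
  } else {
    cat(sprintf("  magnitude excess %.3f (point-estimate call)\n", x$excess))
  }
  if (x$opposing_signs) cat("  note: opposing single-stressor effects\n")
  invisible(x)
}

#' Interaction classification for every trait of a table
#'
#' @inheritParams classify_interaction
#' @param traits Traits to classify (default: all traits in the table).
#' @return A data.frame with one row per trait (deltas, null, deviation,
#'   excess, CI bounds, label, opposing-sign flag).
#' @export
interaction_table <- function(table, traits = trait_names(table),
                              tolerance = 0, n_boot = 2000, seed = 1L,
                              method = c("bootstrap", "point")) {
  method <- match.arg(method)
  rows <- lapply(seq_along(traits), function(i) {
    r <- classify_interaction(table, traits[i], tolerance = tolerance,
                              n_boot = n_boot,
                              seed = as.integer(seed) + i, method = method)
    data.frame(trait = r$trait, delta_temp = r$delta_temp,
               delta_pco2 = r$delta_pco2, delta_combined = r$delta_combined,
               additive_null = r$additive_null, deviation = r$deviation,
               excess = r$excess,
               ci_excess_lo = r$ci_excess[1], ci_excess_hi = r$ci_excess[2],
               label = r$label, opposing_signs = r$opposing_signs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
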
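#' Genotype-mean phenotype array
#'
#' Average value of every trait for each genotype under each treatment — the
#' unit of the tradeoff/broad-spectrum correlation analyses.
#'
#' @param table A trait table.
#' @return A 3-d numeric array `genotype x treatment x trait`.
#' @export
genotype_means <- function(table) {
  table <- validate_trait_table(table)
  gens <- sort(unique(table$genotype_id))
  trts <- intersect(treatment_levels(), unique(table$treatment))
  traits <- trait_names(table)
  arr <- array(NA_real_, dim = c(length(gens), length(trts), length(traits)),
               dimnames = list(genotype = gens, treatment = trts,
                               trait = traits))
  agg <- stats::aggregate(value ~ genotype_id + treatment + trait_name,
                          data = table, FUN = mean)
  arr[cbind(match(agg$genotype_id, gens), match(agg$treatment, trts),
            match(agg$trait_name, traits))] <- agg$value
  if (any(is.na(arr))) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop("no observations for genotype ", gens[miss[1]], " in treatment ",
         trts[miss[2]], " (trait ", traits[miss[3]], ")")
  }
  arr
}

# one Pearson/Spearman test with a zero-variance guard
.cor_entry <- function(x, y, method) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Genotype-mean correlation report
#'
#' Correlations of genotype mean responses, in two modes:
#' `"treatment_by_treatment"` correlates, per trait, the 12 genotype means
#' between every pair of treatments — a significant positive correlation is
#' read as broad-spectrum resistance (genets that do well under one stressor
#' do well under the other), a significant negative one as a tradeoff.
#' `"trait_by_trait"` correlates trait pairs within each treatment.
#' p-values come from the exact t transform of the correlation coefficient
#' (`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df, two-sided), unadjusted at
#' `alpha` by default; a Holm adjustment is reported alongside when
#' requested.
#'
#' @param x A trait table or a [genotype_means()] array.
#' @param mode `"treatment_by_treatment"` (default) or `"trait_by_trait"`.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"` — Holm p-values are added as
#'   `p_holm`/`significant_holm` columns without changing the primary call.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_report`: `mode`, `alpha`,
#'   `method`, and `entries`, a data.frame with the pair labels, `r`, `n`,
#'   `p`, `significant`, and `call` (`tradeoff` when significantly negative,
#'   `broad_spectrum` when significantly positive, else `none`).
#'   Treatment-pair rows among the stress treatments (high_temp, high_pco2,
#'   combined) are tagged `key_comparison`.
#' @export
correlation_report <- function(x, mode = c("treatment_by_treatment",
                                           "trait_by_trait"),
                               alpha = 0.05, adjust = c("none", "holm"),
                               method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  arr <- if (is.array(x) && length(dim(x)) == 3) x else genotype_means(x)
  if (dim(arr)[1] < 3) stop("need at least 3 genotypes for correlations")
  trts <- dimnames(arr)$treatment
  traits <- dimnames(arr)$trait

  rows <- list()
  if (mode == "treatment_by_treatment") {
    pairs <- utils::combn(trts, 2)
    key <- c("high_temp", "high_pco2", "combined")
    for (tr in traits) {
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        e <- .cor_entry(arr[, a, tr], arr[, b, tr], method)
        rows[[length(rows) + 1]] <- data.frame(
          trait = tr, unit_a = a, unit_b = b, r = e$r, n = e$n, p = e$p,
          degenerate = e$degenerate,
          key_comparison = a %in% key && b %in% key,
          stringsAsFactors = FALSE)
      }
    }
  } else {
    if (length(traits) < 2) stop("trait_by_trait mode needs >= 2 traits")
    pairs <- utils::combn(traits, 2)
    for (trt in trts) {
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        e <- .cor_entry(arr[, trt, a], arr[, trt, b], method)
        rows[[length(rows) + 1]] <- data.frame(
          treatment = trt, unit_a = a, unit_b = b, r = e$r, n = e$n, p = e$p,
          degenerate = e$degenerate, key_comparison = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  entries <- do.call(rbind, rows)
  entries$significant <- !is.na(entries$p) & entries$p < alpha
  entries$call <- ifelse(!entries$significant, "none",
                         ifelse(entries$r < 0, "tradeoff", "broad_spectrum"))
  if (adjust == "holm") {
    entries$p_holm <- stats::p.adjust(entries$p, method = "holm")
    entries$significant_holm <- !is.na(entries$p_holm) & entries$p_holm < alpha
  }
  structure(list(mode = mode, alpha = alpha, method = method,
                 adjust = adjust, entries = entries),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  e <- x$entries
  cat("Genotype-mean correlation report (", x$mode, ", ", x$method,
      ", alpha = ", x$alpha, ")\n", sep = "")
  cat(sprintf("  %d pairs: %d broad-spectrum, %d tradeoff, %d none\n",
              nrow(e), sum(e$call == "broad_spectrum"),
              sum(e$call == "tradeoff"), sum(e$call == "none")))
  invisible(x)
}
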
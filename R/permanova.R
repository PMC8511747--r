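#' Build the multivariate phenotype profile matrix
#'
#' Assembles an observations x traits matrix of log-transformed phenotype
#' values for distance-based multivariate analysis. The default analysis unit
#' is the genotype-by-treatment mean (48 rows on the default 12 x 4 design),
#' so that the omnibus test's total degrees of freedom reflect genotype-level
#' replication; fragment-level profiles are available for finer-grained runs.
#'
#' @param table A trait table (see [validate_trait_table()]).
#' @param unit `"genotype_by_treatment"` (default) or `"fragment"`.
#' @param offset Value added to every observation before the natural-log
#'   transform (default 0). Non-positive values under the log raise an error
#'   suggesting an explicit offset rather than silently shifting the data.
#' @return A numeric matrix with one column per trait, log-transformed, with
#'   attribute `groups` giving each row's treatment label. Fragment rows with
#'   any missing trait are dropped (count reported via message).
#' @export
profile_matrix <- function(table, unit = c("genotype_by_treatment", "fragment"),
                           offset = 0) {
  unit <- match.arg(unit)
  table <- validate_trait_table(table)
  traits <- trait_names(table)

  if (unit == "genotype_by_treatment") {
    agg <- stats::aggregate(value ~ genotype_id + treatment + trait_name,
                            data = table, FUN = mean)
    wide <- stats::reshape(agg, idvar = c("genotype_id", "treatment"),
                           timevar = "trait_name", direction = "wide")
    vals <- as.matrix(wide[, paste0("value.", traits), drop = FALSE])
    groups <- wide$treatment
    rn <- paste(wide$genotype_id, wide$treatment, sep = ".")
  } else {
    wide <- stats::reshape(
      table[c("fragment_id", "treatment", "trait_name", "value")],
      idvar = c("fragment_id", "treatment"),
      timevar = "trait_name", direction = "wide")
    vals <- as.matrix(wide[, paste0("value.", traits), drop = FALSE])
    complete <- stats::complete.cases(vals)
    if (any(!complete)) {
      message("profile_matrix: dropped ", sum(!complete),
              " observation(s) with missing traits")
    }
    wide <- wide[complete, , drop = FALSE]
    vals <- vals[complete, , drop = FALSE]
    groups <- wide$treatment
    rn <- wide$fragment_id
  }

  vals <- vals + offset
  if (any(vals <= 0)) {
    stop("non-positive values under the log transform; supply an explicit ",
         "`offset` larger than ", format(-min(vals) + offset),
         " or rescale the affected traits")
  }
  out <- log(vals)
  dimnames(out) <- list(rn, traits)
  attr(out, "groups") <- as.character(groups)
  out
}

# distance matrix for the chosen metric, squared, as a full symmetric matrix
.dist2_matrix <- function(X, metric) {
  d <- switch(metric,
              euclidean   = stats::dist(X),
              bray_curtis = vegan::vegdist(X, method = "bray"))
  as.matrix(d)^2
}

# distance-based partition: within-group and total sums of squares
.permanova_F <- function(d2, gidx, n_per_group, df_between, df_within) {
  ss_within <- 0
  for (g in seq_along(gidx)) {
    idx <- gidx[[g]]
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * n_per_group[g])
  }
  ss_total <- sum(d2) / (2 * nrow(d2))
  ss_between <- ss_total - ss_within
  F <- (ss_between / df_between) / (ss_within / df_within)
  c(F = F, R2 = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance
#'
#' Distance-based one-way PERMANOVA: partitions the total sum of squared
#' pairwise distances into between- and within-group components, forms the
#' pseudo-F ratio, and assesses it by permuting group labels over
#' observations. The p-value uses the `(1 + b)/(1 + n_permutations)`
#' estimator, so it is never exactly zero and its floor is
#' `1/(n_permutations + 1)`.
#'
#' @param X Observation x variable matrix (e.g. from [profile_matrix()]).
#' @param groups Group label per row of `X`.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param metric `"euclidean"` (default) or `"bray_curtis"`.
#' @return An object of class `coral_permanova`: list with `pseudo_F`, `R2`,
#'   `p_perm`, `df_between`, `df_within`, `df_total`, `n_permutations`,
#'   `metric`.
#' @references Anderson, M.J. (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26, 32-46.
#' @export
permanova_test <- function(X, groups, n_permutations = 999, seed = 1L,
                           metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X), n_permutations >= 1)
  tabg <- table(groups)
  if (length(tabg) < 2) stop("need at least 2 groups")
  if (any(tabg < 2)) stop("every group needs at least 2 observations")

  d2 <- .dist2_matrix(X, metric)
  if (all(d2 == 0)) stop("degenerate distance matrix: all distances are zero")

  n <- nrow(d2)
  lev <- names(tabg)
  df_between <- length(lev) - 1L
  df_within <- n - length(lev)
  gsplit <- function(g) split(seq_len(n), factor(g, levels = lev))

  obs <- .permanova_F(d2, gsplit(groups), as.integer(tabg),
                      df_between, df_within)

  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    Fp <- .permanova_F(d2, gsplit(sample(groups)), as.integer(tabg),
                       df_between, df_within)[["F"]]
    if (Fp >= obs[["F"]] - 1e-12) exceed <- exceed + 1L
  }

  structure(
    list(pseudo_F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
         p_perm = (1 + exceed) / (1 + n_permutations),
         df_between = df_between, df_within = df_within, df_total = n - 1L,
         n_permutations = as.integer(n_permutations), metric = metric),
    class = "coral_permanova"
  )
}

#' @export
print.coral_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$metric, " distances)\n", sep = "")
  cat(sprintf("  pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p_perm,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Runs [permanova_test()] on every pair of groups and applies a Bonferroni
#' multiplier equal to the number of pairs. With 999 permutations and 6
#' pairs the minimal attainable adjusted p is `6/1000 = 0.006`.
#'
#' @inheritParams permanova_test
#' @return A data.frame with one row per group pair: `group_a`, `group_b`,
#'   `pseudo_F`, `p_raw`, `p_bonferroni`.
#' @export
pairwise_permanova <- function(X, groups, n_permutations = 999, seed = 1L,
                               metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 3) stop("pairwise comparisons need at least 3 groups")
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  out <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    sel <- groups %in% pairs[, j]
    fit <- permanova_test(X[sel, , drop = FALSE], groups[sel],
                          n_permutations = n_permutations,
                          seed = as.integer(seed) + j, metric = metric)
    out[[j]] <- data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                           pseudo_F = fit$pseudo_F, p_raw = fit$p_perm,
                           p_bonferroni = min(1, fit$p_perm * n_pairs),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
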
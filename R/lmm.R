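#' Fit the per-trait linear mixed model
#'
#' Fits, for one trait, the Gaussian mixed model with fixed treatment,
#' genotype and treatment x genotype effects and a random tank intercept:
#'
#' \deqn{y = X\beta + Z u + e, \quad u \sim N(0, V_{tank} I), \quad
#'       e \sim N(0, V_{res} I).}
#'
#' Variance components are estimated by REML, profiling the single variance
#' ratio \eqn{\lambda = V_{tank}/V_{res}}; fixed effects are the generalized
#' least-squares solution at the REML optimum. The profile is solved to a
#' relative tolerance of about 1e-10 on \eqn{\lambda}, with an explicit check
#' of the \eqn{\lambda = 0} boundary (in which case the fit coincides with
#' ordinary least squares).
#'
#' @param table A trait table.
#' @param trait Trait name to fit.
#' @param ddf_method Default denominator-degrees-of-freedom method for
#'   F-tests: `"containment"` (treatment tested at the tank level, as in a
#'   split-plot ANOVA; exact on balanced designs) or `"satterthwaite"`.
#' @return An object of class `coral_lmm` with components `beta` (labelled
#'   fixed effects, sum-to-zero coding), `V_tank`, `V_residual`, `lambda`,
#'   `reml_loglik`, `vcov_beta`, and design bookkeeping used by
#'   [anova.coral_lmm()] and [tukey_hsd()].
#' @export
fit_trait_lmm <- function(table, trait,
                          ddf_method = c("containment", "satterthwaite")) {
  ddf_method <- match.arg(ddf_method)
  table <- validate_trait_table(table)
  d <- .trait_subset(table, trait)

  cell <- table(d$genotype_id, d$treatment)
  if (any(cell == 0)) {
    empty <- which(cell == 0, arr.ind = TRUE)[1, ]
    stop("singular design: genotype ", rownames(cell)[empty[1]],
         " has no observations in treatment ", colnames(cell)[empty[2]])
  }
  tanks_per_trt <- table(unique(d[c("tank_id", "treatment")])$treatment)
  if (any(tanks_per_trt < 2)) {
    stop("need at least 2 tanks per treatment for the tank random effect")
  }

  # canonical row order makes the fit exactly invariant to input ordering
  d <- d[order(d$tank_id, d$genotype_id, d$fragment_id), , drop = FALSE]
  y <- d$value
  X <- stats::model.matrix(~ treatment * genotype_id, d,
                           contrasts.arg = list(treatment = "contr.sum",
                                                genotype_id = "contr.sum"))
  assign <- attr(X, "assign")
  tank <- droplevels(d$tank_id)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is rank deficient")

  m <- as.vector(table(tank))              # fragments per tank
  TX <- rowsum(X, tank)                     # tank sums of design rows
  Ty <- as.vector(rowsum(y, tank))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  # REML profile pieces at a given variance ratio lambda (Woodbury identity:
  # Vinv = I - Z diag(lambda/(1+lambda*m)) Z' for tank-partitioned Z)
  profile_at <- function(lambda) {
    w <- lambda / (1 + lambda * m)
    XtViX <- XtX - crossprod(TX, w * TX)
    XtViy <- Xty - crossprod(TX, w * Ty)
    ytViy <- yty - sum(w * Ty^2)
    R <- chol(XtViX)
    beta <- backsolve(R, forwardsolve(t(R), XtViy))
    sse <- max(ytViy - sum(beta * XtViy), 0)
    sigma2 <- sse / (n - p)
    crit <- (n - p) * log(sigma2) + sum(log1p(lambda * m)) +
      2 * sum(log(diag(R)))
    list(crit = crit, beta = as.vector(beta), sigma2 = sigma2,
         XtViX = XtViX, R = R)
  }
  crit_of <- function(loglam) profile_at(exp(loglam))$crit

  grid <- seq(-14, 12, by = 1)
  gvals <- vapply(grid, crit_of, 0)
  c0 <- profile_at(0)$crit
  if (min(gvals) >= c0 - 1e-9) {
    lambda <- 0
  } else {
    i <- which.min(gvals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(crit_of, interval = c(lo, hi), tol = 1e-11)
    lambda <- exp(opt$minimum)
    if (profile_at(0)$crit <= opt$objective + 1e-9) lambda <- 0
  }

  fit <- profile_at(lambda)
  sigma2 <- fit$sigma2
  XtViXinv <- chol2inv(fit$R)
  beta <- stats::setNames(fit$beta, colnames(X))
  reml_loglik <- -0.5 * (fit$crit + (n - p) * (1 + log(2 * pi)))

  structure(
    list(trait = trait, beta = beta, V_tank = lambda * sigma2,
         V_residual = sigma2, lambda = lambda,
         reml_loglik = as.numeric(reml_loglik),
         vcov_beta = sigma2 * XtViXinv,
         assign = assign, term_labels = attr(stats::terms(~ treatment * genotype_id),
                                             "term.labels"),
         n = n, p = p, n_tanks = length(m), m = m,
         n_treatments = nlevels(d$treatment),
         treatment_levels = levels(d$treatment),
         genotype_levels = levels(d$genotype_id),
         data = d, X = X, y = y, tank = tank,
         ddf_method = ddf_method),
    class = "coral_lmm"
  )
}

#' @export
print.coral_lmm <- function(x, ...) {
  cat("Linear mixed model for trait '", x$trait, "'\n", sep = "")
  cat(sprintf("  REML log-likelihood: %.3f\n", x$reml_loglik))
  cat(sprintf("  V_tank = %.5g, V_residual = %.5g (ratio %.4g)\n",
              x$V_tank, x$V_residual, x$lambda))
  cat("  fixed effects: treatment * genotype (sum-to-zero coding)\n")
  invisible(x)
}

# full REML deviance (-2 logLik, up to constant) as a function of (Vt, Ve);
# used for the Satterthwaite variance of the variance-component estimates
.reml_deviance <- function(fit, theta) {
  Vt <- theta[1]; Ve <- theta[2]
  lambda <- Vt / Ve
  m <- fit$m
  X <- fit$X; y <- fit$y; tank <- fit$tank
  w <- lambda / (1 + lambda * m)
  TX <- rowsum(X, tank); Ty <- as.vector(rowsum(y, tank))
  XtViX <- crossprod(X) - crossprod(TX, w * TX)
  XtViy <- crossprod(X, y) - crossprod(TX, w * Ty)
  ytViy <- sum(y^2) - sum(w * Ty^2)
  R <- chol(XtViX)
  beta <- backsolve(R, forwardsolve(t(R), XtViy))
  sse <- ytViy - sum(beta * XtViy)
  n <- fit$n; p <- fit$p
  (n - p) * log(Ve) + sum(log1p(lambda * m)) + 2 * sum(log(diag(R))) +
    sse / Ve
}

# covariance of beta-hat as a function of (Vt, Ve)
.beta_cov_at <- function(fit, theta) {
  lambda <- theta[1] / theta[2]
  w <- lambda / (1 + lambda * fit$m)
  TX <- rowsum(fit$X, fit$tank)
  XtViX <- crossprod(fit$X) - crossprod(TX, w * TX)
  theta[2] * chol2inv(chol(XtViX))
}

# Satterthwaite denominator df for the F-test defined by contrast rows L
.satterthwaite_df <- function(fit, L) {
  theta <- c(max(fit$V_tank, 1e-8 * fit$V_residual), fit$V_residual)
  H <- stats::optimHess(theta, function(th) .reml_deviance(fit, th))
  A <- tryCatch(2 * solve(H), error = function(e) matrix(NA, 2, 2))
  M <- L %*% fit$vcov_beta %*% t(L)
  eg <- eigen(M, symmetric = TRUE)
  q <- nrow(L)
  nu <- numeric(q)
  h <- vapply(theta, function(t) max(1e-7, 1e-5 * t), 0)
  for (i in seq_len(q)) {
    l <- as.vector(t(L) %*% eg$vectors[, i])
    f <- function(th) as.numeric(l %*% .beta_cov_at(fit, th) %*% l)
    g <- vapply(1:2, function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], 1e-12)
      (f(tp) - f(tm)) / (tp[k] - tm[k])
    }, 0)
    denom <- as.numeric(g %*% A %*% g)
    nu[i] <- if (is.finite(denom) && denom > 0) 2 * eg$values[i]^2 / denom else Inf
  }
  if (q == 1) return(nu)
  nu_ok <- nu[nu > 2]
  if (length(nu_ok) == 0) return(Inf)
  E <- sum(nu_ok / (nu_ok - 2))
  if (E > q) 2 * E / (E - q) else Inf
}

#' F-tests for the mixed-model fixed effects
#'
#' Wald F statistics for treatment, genotype and their interaction, using the
#' REML-estimated covariance of the fixed effects. Denominator degrees of
#' freedom follow the containment rule by default — the treatment effect is
#' replicated at the tank level, so its denominator df is
#' `n_tanks - n_treatments` (16 on the default design), while genotype and
#' interaction are tested at the residual level — or Satterthwaite's
#' approximation on request.
#'
#' @param object A `coral_lmm` fit.
#' @param ddf_method `"containment"` or `"satterthwaite"` (defaults to the
#'   method chosen at fit time).
#' @param ... Unused.
#' @return A data.frame with one row per term: `term`, `F`, `df_num`,
#'   `df_den`, `p`.
#' @export
anova.coral_lmm <- function(object, ddf_method = NULL, ...) {
  if (is.null(ddf_method)) ddf_method <- object$ddf_method
  ddf_method <- match.arg(ddf_method, c("containment", "satterthwaite"))
  if (object$V_residual <= 0) stop("zero residual variance: F-tests undefined")

  terms <- object$term_labels  # treatment, genotype_id, interaction
  ddf_contain <- c(object$n_tanks - object$n_treatments,
                   rep(object$n - object$p -
                         (object$n_tanks - object$n_treatments), 2))
  out <- vector("list", length(terms))
  for (t in seq_along(terms)) {
    idx <- which(object$assign == t)
    q <- length(idx)
    b <- object$beta[idx]
    Cb <- object$vcov_beta[idx, idx, drop = FALSE]
    Fstat <- as.numeric(b %*% solve(Cb, b)) / q
    ddf <- if (ddf_method == "containment") {
      ddf_contain[t]
    } else {
      L <- matrix(0, q, object$p)
      L[cbind(seq_len(q), idx)] <- 1
      .satterthwaite_df(object, L)
    }
    out[[t]] <- data.frame(term = terms[t], F = Fstat, df_num = q,
                           df_den = ddf,
                           p = stats::pf(Fstat, q, ddf, lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$term <- sub("genotype_id", "genotype", res$term)
  res$term <- sub("treatment:genotype", "treatment:genotype", res$term)
  rownames(res) <- NULL
  res
}

#' Tukey HSD comparisons among treatments
#'
#' All pairwise treatment mean differences (marginal over genotypes) with
#' familywise-adjusted p-values from the studentized range distribution,
#' using the treatment test's denominator degrees of freedom.
#'
#' @param fit A `coral_lmm` fit.
#' @param factor Factor to compare; only `"treatment"` is supported.
#' @return A data.frame with `level_a`, `level_b`, `estimate` (mean
#'   difference a - b), `se`, `p_adjusted`.
#' @export
tukey_hsd <- function(fit, factor = "treatment") {
  stopifnot(inherits(fit, "coral_lmm"))
  factor <- match.arg(factor, "treatment")
  lev <- fit$treatment_levels
  if (length(lev) < 2) stop("need at least 2 treatment levels")

  grid <- expand.grid(treatment = factor(lev, levels = lev),
                      genotype_id = factor(fit$genotype_levels,
                                           levels = fit$genotype_levels))
  Mg <- stats::model.matrix(~ treatment * genotype_id, grid,
                            contrasts.arg = list(treatment = "contr.sum",
                                                 genotype_id = "contr.sum"))
  Lt <- rowsum(Mg, grid$treatment) / length(fit$genotype_levels)

  ddf <- fit$n_tanks - fit$n_treatments
  nmeans <- length(lev)
  pairs <- utils::combn(lev, 2)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    l <- Lt[pairs[1, j], ] - Lt[pairs[2, j], ]
    est <- sum(l * fit$beta)
    v <- as.numeric(l %*% fit$vcov_beta %*% l)
    qstat <- abs(est) / sqrt(v / 2)
    out[[j]] <- data.frame(level_a = pairs[1, j], level_b = pairs[2, j],
                           estimate = est, se = sqrt(v),
                           p_adjusted = stats::ptukey(qstat, nmeans, ddf,
                                                      lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
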
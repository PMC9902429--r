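#' Centre and scale each metabolite
#'
#' Every metabolite row is shifted to mean zero and scaled to unit SD, so
#' downstream log-fold changes are in standardized natural-log units and
#' directly comparable across metabolites.
#'
#' @param x a complete `abundance_matrix`.
#' @return The standardized matrix (scale tag unchanged).
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (anyNA(x$values)) stop("standardize() requires a complete matrix")
  sds <- apply(x$values, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-SD metabolite(s) (filter first): ",
         paste(rownames(x$values)[sds == 0], collapse = ", "))
  set_values(x, (x$values - rowMeans(x$values)) / sds)
}

# internal: fixed-effects design matrix for the region design
region_design <- function(samples, covariates = c("age", "sex", "batch"),
                          interactions = character(0)) {
  terms <- c("region", covariates, interactions)
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  sm <- samples
  sm$age <- sm$age - mean(sm$age)
  X <- stats::model.matrix(f, data = sm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

# internal: contrast matrix for macula/temporal/periphery with treatment coding
# (intercept = macula level when region levels are macula, temporal, periphery)
region_contrasts <- function(X) {
  cn <- colnames(X)
  ct <- matrix(0, length(cn), 3,
               dimnames = list(cn, c("macula_vs_temporal", "temporal_vs_periphery",
                                     "macula_vs_periphery")))
  if (!all(c("regiontemporal", "regionperiphery") %in% cn))
    stop("design lacks region columns")
  ct["regiontemporal", ] <- c(-1, 1, 0)
  ct["regionperiphery", ] <- c(0, -1, -1)
  ct
}

#' Consensus within-subject correlation
#'
#' Estimates, for each metabolite, the within-block (within-subject)
#' correlation of residuals from the ordinary fixed-effects fit by method of
#' moments: the mean pairwise residual cross-product within blocks divided by
#' the mean squared residual, with a first-order `p/n` correction for the
#' downward bias that residualizing on `p` design columns induces. The
#' consensus is the hyperbolic tangent of the 10%-trimmed mean of the
#' per-metabolite atanh values, clipped to (-0.99, 0.99) — one shared
#' correlation, stable at small sample sizes.
#'
#' Only design columns that vary within at least one block enter the
#' residualization: block-constant covariates (age, sex, batch in a design
#' with few subjects) are confounded with the block effect itself, and
#' projecting them out would absorb exactly the between-sample covariance
#' this function is trying to measure.
#'
#' @param x a standardized complete `abundance_matrix`.
#' @param samples sample table; `block` names the grouping column.
#' @param design fixed-effects design matrix (default: the region design).
#' @param block column of `samples` defining blocks.
#' @param trim trimming fraction of the atanh average.
#' @return List of class `consensus_correlation`: `consensus`, `per_metabolite`,
#'   `n_used`.
#' @export
estimate_consensus_correlation <- function(x, samples,
                                           design = NULL,
                                           block = "subject_id",
                                           trim = 0.10) {
  stopifnot(inherits(x, "abundance_matrix"))
  samples <- align_samples(x, samples)
  if (is.null(design)) design <- region_design(samples)
  blocks <- as.character(samples[[block]])
  multi <- names(which(table(blocks) >= 2))
  if (length(multi) < 2) stop("need >=2 blocks with >=2 samples")
  Y <- x$values
  # drop block-constant columns (keep the intercept)
  varies <- vapply(seq_len(ncol(design)), function(j) {
    any(tapply(design[, j], blocks, function(v) length(unique(v)) > 1))
  }, TRUE)
  varies[1] <- TRUE
  design <- design[, varies, drop = FALSE]
  qrX <- qr(design)
  R <- t(Y) - design %*% qr.coef(qrX, t(Y))       # residuals, samples x metabolites
  rho <- apply(R, 2, function(r) {
    num <- 0; npair <- 0
    for (b in multi) {
      rb <- r[blocks == b]
      s <- sum(rb)^2 - sum(rb^2)
      num <- num + s
      npair <- npair + length(rb) * (length(rb) - 1)
    }
    denom <- mean(r^2)
    if (denom <= 0 || npair == 0) return(NA_real_)
    (num / npair) / denom
  })
  rho <- rho[is.finite(rho)]
  # first-order small-sample correction: OLS residualization on p columns
  # shrinks within-block cross-products by roughly p/n
  p_used <- ncol(design)
  n <- nrow(design)
  rho <- rho + (p_used / n) * (1 - rho)
  rho <- pmin(pmax(rho, -0.99), 0.99)
  consensus <- tanh(mean(atanh(rho), trim = trim))
  consensus <- min(max(consensus, -0.99), 0.99)
  structure(list(consensus = consensus, per_metabolite = rho,
                 n_used = length(rho)), class = "consensus_correlation")
}

#' @export
print.consensus_correlation <- function(x, ...) {
  cat(sprintf("consensus within-block correlation: %.3f (from %d metabolites)\n",
              x$consensus, x$n_used))
  invisible(x)
}

# internal: block-diagonal whitening matrix for compound symmetry with a
# shared rho: Sigma_b = (1-rho) I + rho J, W_b = Sigma_b^{-1/2}
cs_whitening <- function(blocks, rho) {
  n <- length(blocks)
  W <- matrix(0, n, n)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    if (k == 1) { W[idx, idx] <- 1 / sqrt(1 + 0) ; next }
    # eigenvalues: 1 + (k-1) rho (ones direction), 1 - rho (complement)
    l1 <- 1 + (k - 1) * rho
    l2 <- 1 - rho
    if (l1 <= 0 || l2 <= 0) stop("compound-symmetry covariance not positive definite")
    J <- matrix(1 / k, k, k)
    W[idx, idx] <- J / sqrt(l1) + (diag(k) - J) / sqrt(l2)
  }
  W
}

#' Fit the moderated regional abundance model
#'
#' The central fitting function. Per metabolite, a generalized least squares
#' fit of standardized log abundance on region plus covariates (age, sex,
#' batch by default) under a compound-symmetry within-subject covariance with
#' one consensus correlation; residual variances are then shrunk towards a
#' scaled-inverse-chi-square prior estimated from all metabolites by
#' empirical Bayes (moment matching on log variances), and the three region
#' contrasts (macula-temporal, temporal-periphery, macula-periphery) are
#' tested with moderated t-statistics.
#'
#' @param x a complete, standardized (or at least complete) `abundance_matrix`.
#' @param samples sample table.
#' @param covariates covariate columns included in the design.
#' @param interactions optional interaction terms (e.g. `"age:region"`).
#' @param block blocking column for the within-subject correlation; `NULL`
#'   fits ordinary least squares (rho = 0).
#' @param rho within-block correlation; `NULL` estimates the consensus from
#'   the data via [estimate_consensus_correlation()].
#' @param moderate if `FALSE`, skip empirical-Bayes shrinkage (d0 = 0), so
#'   moderated t reduces to the ordinary t.
#' @param formula optional model formula over `samples` columns replacing the
#'   default region design (used e.g. for case/control serum studies); when
#'   given, `contrast_matrix` must be supplied too.
#' @param contrast_matrix optional terms x contrasts matrix; defaults to the
#'   three region contrasts.
#' @return An object of class `abundance_fit` with components `coefficients`
#'   (metabolites x terms), `stdev_unscaled`, `sigma2`, `df_residual`,
#'   `prior` (`d0`, `s0_sq`), `sigma2_post`, `contrast_matrix`, `design`,
#'   `correlation`, `effects_signal`, `effects_residual` (for rotation
#'   tests).
#' @export
fit_abundance_model <- function(x, samples,
                                covariates = c("age", "sex", "batch"),
                                interactions = character(0),
                                block = "subject_id",
                                rho = NULL,
                                moderate = TRUE,
                                formula = NULL,
                                contrast_matrix = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (anyNA(x$values)) stop("fit requires a complete matrix; impute first")
  samples <- if ("sample_id" %in% names(samples) && is.null(formula))
    align_samples(x, samples) else {
      if (!all(sample_ids(x) %in% samples$sample_id))
        stop("samples missing from the sample table")
      samples[match(sample_ids(x), samples$sample_id), , drop = FALSE]
    }
  if (is.null(formula)) {
    X <- region_design(samples, covariates, interactions)
    if (is.null(contrast_matrix)) contrast_matrix <- region_contrasts(X)
  } else {
    sm <- samples
    if ("age" %in% names(sm) && is.numeric(sm$age)) sm$age <- sm$age - mean(sm$age)
    X <- stats::model.matrix(formula, data = sm)
    if (is.null(contrast_matrix))
      stop("supply a contrast_matrix when using a custom formula")
  }
  corr <- NULL
  if (is.null(rho)) {
    if (is.null(block)) {
      rho <- 0
    } else {
      corr <- estimate_consensus_correlation(x, samples, design = X, block = block)
      rho <- corr$consensus
    }
  }
  blocks <- if (is.null(block)) as.character(seq_len(nrow(samples)))
            else as.character(samples[[block]])
  W <- if (rho == 0) diag(nrow(X)) else cs_whitening(blocks, rho)
  Xw <- W %*% X
  Yw <- x$values %*% t(W)                      # metabolites x samples, whitened
  qrX <- qr(Xw)
  p <- qrX$rank
  n <- ncol(Yw)
  if (p < ncol(Xw)) stop("whitened design is rank deficient")
  B <- t(qr.coef(qrX, t(Yw)))                  # metabolites x p coefficients
  fitted <- B %*% t(Xw)
  res <- Yw - fitted
  d <- n - p
  sigma2 <- rowSums(res^2) / d
  XtXi <- chol2inv(qr.R(qrX))
  dimnames(XtXi) <- list(colnames(Xw), colnames(Xw))
  prior <- if (moderate) moderate_variances(sigma2, d) else
    list(d0 = 0, s0_sq = NA_real_, sigma2_post = sigma2)
  fit <- structure(list(
    coefficients = B,
    sigma2 = sigma2,
    df_residual = d,
    cov_unscaled = XtXi,
    prior = list(d0 = prior$d0, s0_sq = prior$s0_sq),
    sigma2_post = prior$sigma2_post,
    contrast_matrix = contrast_matrix,
    design = X, whitening = W, design_whitened = Xw,
    correlation = rho, consensus = corr,
    qr = qrX, residuals_whitened = res,
    metabolite_ids = rownames(x$values),
    samples = samples), class = "abundance_fit")
  fit
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled-inverse-chi-square prior (`d0`, `s0_sq`) to the observed
#' residual variances by matching the first two moments of `log(s^2)`
#' (digamma/trigamma inversion), then returns the posterior variances
#' `(d0*s0_sq + d*s2) / (d0 + d)`. When the trigamma equation has no positive
#' solution the prior is degenerate (`d0 = Inf`) and every posterior variance
#' equals `s0_sq`.
#'
#' @param s2 vector of residual variances (all > 0).
#' @param d residual degrees of freedom (shared).
#' @return List with `d0`, `s0_sq`, `sigma2_post`.
#' @export
moderate_variances <- function(s2, d) {
  if (length(s2) < 3) stop("need at least 3 metabolites to estimate the prior")
  if (any(s2 <= 0)) stop("residual variances must be positive")
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e)
  rhs <- evar - trigamma(d / 2)
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_sq + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
    post <- rep(s0_sq, length(s2))
  }
  list(d0 = d0, s0_sq = s0_sq, sigma2_post = post)
}

# Newton inversion of the trigamma function (y > 0)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated contrast tests
#'
#' Computes, for each metabolite and each contrast, the estimated log-fold
#' change, the moderated t-statistic (contrast estimate over its standard
#' error with the posterior variance), the p-value on `d0 + d` degrees of
#' freedom (normal when `d0` is infinite), the Benjamini-Hochberg adjusted
#' p-value within each contrast, and a significance flag.
#'
#' @param fit an `abundance_fit`.
#' @param fdr_cutoff significance cutoff on the adjusted p-value.
#' @return Data frame of class `contrast_results`: `metabolite_id`,
#'   `contrast`, `logFC`, `t`, `p`, `fdr`, `significant`.
#' @export
test_contrasts <- function(fit, fdr_cutoff = 0.05) {
  stopifnot(inherits(fit, "abundance_fit"))
  ct <- fit$contrast_matrix
  est <- fit$coefficients %*% ct                      # metabolites x contrasts
  se_unscaled <- sqrt(diag(t(ct) %*% fit$cov_unscaled %*% ct))
  se <- sqrt(fit$sigma2_post) %o% se_unscaled
  tstat <- est / se
  df_total <- fit$prior$d0 + fit$df_residual
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = df_total)
  out <- do.call(rbind, lapply(seq_len(ncol(ct)), function(j) {
    fdr <- stats::p.adjust(p[, j], method = "BH")
    data.frame(metabolite_id = fit$metabolite_ids,
               contrast = colnames(ct)[j],
               logFC = est[, j], t = tstat[, j], p = p[, j], fdr = fdr,
               significant = fdr < fdr_cutoff,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("contrast_results", "data.frame")
  out
}

#' Covariate effect table
#'
#' Moderated tests of the non-region model coefficients (sex, age, batch and
#' any interaction terms) for every metabolite.
#'
#' @param fit an `abundance_fit`.
#' @param fdr_cutoff significance cutoff.
#' @return Data frame: `metabolite_id`, `term`, `estimate`, `t`, `p`, `fdr`.
#' @export
covariate_effects <- function(fit, fdr_cutoff = 0.05) {
  stopifnot(inherits(fit, "abundance_fit"))
  terms <- setdiff(colnames(fit$coefficients),
                   c("(Intercept)", "regiontemporal", "regionperiphery"))
  df_total <- fit$prior$d0 + fit$df_residual
  out <- do.call(rbind, lapply(terms, function(tm) {
    est <- fit$coefficients[, tm]
    se <- sqrt(fit$sigma2_post * fit$cov_unscaled[tm, tm])
    tstat <- est / se
    p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
      2 * stats::pt(-abs(tstat), df = df_total)
    data.frame(metabolite_id = fit$metabolite_ids, term = tm,
               estimate = est, t = tstat, p = p,
               fdr = stats::p.adjust(p, method = "BH"),
               significant = stats::p.adjust(p, method = "BH") < fdr_cutoff,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("abundance_fit: %d metabolites, %d samples, %d coefficients\n",
              nrow(x$coefficients), nrow(x$design), ncol(x$coefficients)))
  cat(sprintf("  within-block correlation: %.3f%s\n", x$correlation,
              if (!is.null(x$consensus)) " (consensus estimate)" else ""))
  cat(sprintf("  residual df: %d; prior df d0: %s; prior variance s0^2: %s\n",
              x$df_residual, format(x$prior$d0, digits = 4),
              format(x$prior$s0_sq, digits = 4)))
  invisible(x)
}

#' @export
summary.abundance_fit <- function(object, fdr_cutoff = 0.05, ...) {
  res <- test_contrasts(object, fdr_cutoff = fdr_cutoff)
  counts <- tapply(res$significant, res$contrast, sum)
  structure(list(fit = object, results = res, n_significant = counts,
                 fdr_cutoff = fdr_cutoff), class = "summary.abundance_fit")
}

#' @export
print.summary.abundance_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  significant metabolites at FDR < %.2g:\n", x$fdr_cutoff))
  for (nm in names(x$n_significant))
    cat(sprintf("    %-22s %d\n", nm, x$n_significant[[nm]]))
  invisible(x)
}

#' @export
coef.abundance_fit <- function(object, ...) object$coefficients

#' @export
residuals.abundance_fit <- function(object, ...) object$residuals_whitened
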
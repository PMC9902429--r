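#' Iterative random-forest imputation for MAR metabolites
#'
#' missForest-style conditional modelling: missing cells start at their
#' metabolite mean, then each incomplete target metabolite is repeatedly
#' regressed (random-forest, `ranger`) on all other metabolites and its
#' missing cells replaced by the forest predictions, sweeping metabolites in
#' increasing order of missingness until the root-mean-square change between
#' successive sweeps falls below `tol` or `max_sweeps` is reached. Observed
#' cells are never modified.
#'
#' @param x an `abundance_matrix` on the normalized log scale.
#' @param mar_ids metabolites to impute (default: all incomplete ones).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @param mtry predictors tried per split; the default uses all of them
#'   (bagged trees): with a few dozen samples and many mutually correlated
#'   predictors, predictor subsampling mostly injects noise.
#' @param min_node_size minimum terminal-node size.
#' @param tol RMS convergence tolerance.
#' @param max_sweeps maximum number of sweeps.
#' @return The matrix with the listed metabolites completed.
#' @export
impute_mar <- function(x, mar_ids = NULL, seed = 1L, num_trees = 100L,
                       mtry = NULL, min_node_size = 2L,
                       tol = 1e-3, max_sweeps = 10L) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  if (is.null(mar_ids)) mar_ids <- rownames(v)[rowSums(is.na(v)) > 0]
  mar_ids <- intersect(mar_ids, rownames(v))
  if (!length(mar_ids) || !anyNA(v[mar_ids, , drop = FALSE])) return(x)
  fully_missing <- mar_ids[rowSums(!is.na(v[mar_ids, , drop = FALSE])) == 0]
  if (length(fully_missing))
    stop("metabolite(s) fully missing (filter first): ",
         paste(fully_missing, collapse = ", "))
  mask <- is.na(v)
  filled <- v
  rmean <- rowMeans(v, na.rm = TRUE)
  for (id in rownames(v)) filled[id, mask[id, ]] <- rmean[id]
  # samples x metabolites frame for the forests
  ord <- mar_ids[order(rowSums(mask[mar_ids, , drop = FALSE]))]
  set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max - 1L, max_sweeps * length(ord))
  k <- 0L
  for (sweep in seq_len(max_sweeps)) {
    prev <- filled
    for (id in ord) {
      k <- k + 1L
      holes <- mask[id, ]
      df <- as.data.frame(t(filled[setdiff(rownames(v), id), , drop = FALSE]))
      names(df) <- paste0("x", seq_along(df))   # syntactic names for ranger
      df$.y <- filled[id, ]
      fit <- ranger::ranger(dependent.variable.name = ".y",
                            data = df[!holes, , drop = FALSE],
                            num.trees = num_trees,
                            mtry = if (is.null(mtry)) ncol(df) - 1L else mtry,
                            min.node.size = min_node_size,
                            seed = sweep_seeds[k],
                            num.threads = 1L, verbose = FALSE)
      filled[id, holes] <- stats::predict(fit, df[holes, , drop = FALSE],
                                          num.threads = 1L)$predictions
    }
    delta <- sqrt(mean((filled[mask] - prev[mask])^2))
    if (delta < tol) break
  }
  filled[!mask] <- v[!mask]   # contract: observed cells bit-identical
  set_values(x, filled)
}

#' Truncated-Gaussian Gibbs imputation for MNAR metabolites
#'
#' Treats each MNAR metabolite's missing cells as left-censored below that
#' metabolite's observed minimum (a detection-limit proxy). A Gibbs sampler
#' alternates between (a) drawing the censored cells from the conditional
#' Gaussian given a linear model on the metabolite's two auxiliary
#' metabolites, truncated above at the censoring bound, and (b) redrawing the
#' regression coefficients and residual variance from their conditional
#' posterior given the completed data (flat prior). The imputed value is the
#' posterior mean over the kept sweeps. Cells whose auxiliaries are
#' themselves missing fall back to a marginal truncated-Gaussian draw.
#'
#' @param x an `abundance_matrix` on the normalized log scale.
#' @param mnar_ids metabolites to impute.
#' @param report a [missingness_report()] supplying the auxiliary pairs.
#' @param seed integer seed.
#' @param n_burn,n_keep burn-in and kept Gibbs sweeps.
#' @return The matrix with the listed metabolites completed; every imputed
#'   value is at or below the metabolite's observed minimum.
#' @export
impute_mnar <- function(x, mnar_ids, report, seed = 1L,
                        n_burn = 100L, n_keep = 400L) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  mnar_ids <- intersect(mnar_ids, rownames(v))
  set.seed(seed + 7L)
  for (id in mnar_ids) {
    y <- v[id, ]
    holes <- which(is.na(y))
    if (!length(holes)) next
    obs <- which(!is.na(y))
    if (length(obs) < 3) stop("metabolite '", id, "' has <3 observed values")
    bound <- min(y[obs])
    rrow <- report[report$metabolite_id == id, , drop = FALSE]
    aux <- NULL
    if (nrow(rrow) == 1 && !is.na(rrow$aux1_id))
      aux <- rbind(v[rrow$aux1_id, ], v[rrow$aux2_id, ])
    v[id, holes] <- gibbs_censored(y, holes, obs, bound, aux,
                                   n_burn = n_burn, n_keep = n_keep)
  }
  set_values(x, v)
}

# one metabolite's left-censored Gibbs sampler; returns posterior-mean imputations
gibbs_censored <- function(y, holes, obs, bound, aux, n_burn, n_keep) {
  obs_fit <- obs
  usable <- integer(0)
  X <- NULL
  if (!is.null(aux)) {
    X <- cbind(1, t(aux))
    obs_fit <- obs[stats::complete.cases(X[obs, , drop = FALSE])]
    if (length(obs_fit) >= ncol(X) + 2)
      usable <- holes[stats::complete.cases(X[holes, , drop = FALSE])]
    else obs_fit <- obs
  }
  have_aux <- length(usable) > 0
  fallback <- setdiff(holes, usable)
  mu0 <- mean(y[obs]); sd0 <- stats::sd(y[obs])
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- 1e-6
  yy <- y
  yy[holes] <- bound - abs(stats::rnorm(length(holes), 0, sd0))  # start below bound
  acc <- numeric(length(holes)); names(acc) <- as.character(holes)
  total <- n_burn + n_keep
  for (it in seq_len(total)) {
    if (have_aux && length(usable)) {
      fit_idx <- c(obs_fit, usable)
      Xf <- X[fit_idx, , drop = FALSE]
      qrX <- qr(Xf)
      beta_hat <- qr.coef(qrX, yy[fit_idx])
      beta_hat[is.na(beta_hat)] <- 0
      res <- yy[fit_idx] - X[fit_idx, , drop = FALSE] %*% beta_hat
      df <- max(length(fit_idx) - ncol(Xf), 1)
      sig2 <- sum(res^2) / stats::rchisq(1, df)
      XtXi <- chol2inv(qr.R(qrX))
      beta <- beta_hat + drop(t(chol(sig2 * XtXi + diag(1e-10, ncol(Xf)))) %*%
                                stats::rnorm(ncol(Xf)))
      mu_cells <- drop(X[usable, , drop = FALSE] %*% beta)
      yy[usable] <- rtruncnorm_upper(mu_cells, sqrt(sig2), bound)
    }
    if (length(fallback)) {
      m <- mean(yy[c(obs, holes)]); s <- stats::sd(yy[c(obs, holes)])
      if (!is.finite(s) || s <= 0) s <- sd0
      yy[fallback] <- rtruncnorm_upper(rep(m, length(fallback)), s, bound)
    }
    if (it > n_burn) acc <- acc + yy[holes]
  }
  acc / n_keep
}

# draw from N(mu, sd^2) truncated above at `upper` by inverse-CDF
rtruncnorm_upper <- function(mu, sd, upper) {
  p <- stats::pnorm(upper, mu, sd)
  p <- pmax(p, 1e-12)
  u <- stats::runif(length(mu)) * p
  q <- stats::qnorm(pmin(u, p * (1 - 1e-12)), mu, sd)
  pmin(q, upper)
}

#' Mechanism-aware imputation
#'
#' Routes metabolites by their classified mechanism: MAR and UNTESTABLE_MAR
#' metabolites go through the iterative random-forest imputer, MNAR
#' metabolites through the left-censored Gibbs sampler (run on the
#' MAR-completed matrix so forests see maximal information). The result is a
#' complete matrix tagged `scale = "imputed"`.
#'
#' @param x an `abundance_matrix` on the normalized log scale.
#' @param report a [missingness_report()] covering every incomplete metabolite.
#' @param seed integer seed.
#' @param ... passed to [impute_mar()].
#' @return A complete `abundance_matrix` with `scale = "imputed"`.
#' @export
impute_abundance <- function(x, report, seed = 1L, ...) {
  stopifnot(inherits(x, "abundance_matrix"))
  incomplete <- rownames(x$values)[rowSums(is.na(x$values)) > 0]
  uncovered <- setdiff(incomplete, report$metabolite_id)
  if (length(uncovered))
    stop("metabolite(s) with missing values absent from the mechanism report: ",
         paste(uncovered, collapse = ", "))
  mech <- stats::setNames(report$mechanism, report$metabolite_id)
  mar_ids <- names(mech)[mech %in% c("MAR", "UNTESTABLE_MAR")]
  mnar_ids <- names(mech)[mech == "MNAR"]
  out <- x
  if (length(mnar_ids)) {
    # impute MNAR first from observed data only, then let the forests use them
    out <- impute_mnar(out, mnar_ids, report, seed = seed)
  }
  if (length(mar_ids)) out <- impute_mar(out, mar_ids, seed = seed, ...)
  if (anyNA(out$values)) stop("imputation left missing cells behind")
  set_values(out, out$values, scale = "imputed")
}
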
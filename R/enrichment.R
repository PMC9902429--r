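# Rotation machinery -----------------------------------------------------
#
# After whitening, the data for metabolite m reduce (via the QR of the
# reparametrized design) to a (d+1)-vector z_m whose first component carries
# the contrast of interest and whose remaining d components span residual
# space; under the null all components are iid N(0, sigma_m^2). A random
# rotation draws one uniform unit vector r in R^{d+1} and, for every
# metabolite simultaneously, recomputes the moderated t from z1* = r'z_m and
# s*^2 = (||z_m||^2 - z1*^2)/d. Sharing r across metabolites preserves the
# inter-metabolite correlation structure, which is what makes the set test
# valid for correlated members.

# internal: per-metabolite z-vectors (metabolites x (d+1)) for one contrast
contrast_effects <- function(fit, contrast) {
  ct <- fit$contrast_matrix
  if (is.character(contrast)) {
    if (!contrast %in% colnames(ct)) stop("unknown contrast: ", contrast)
    cvec <- ct[, contrast]
  } else cvec <- contrast
  X <- fit$design_whitened
  n <- nrow(X); p <- ncol(X)
  # reparametrize so the contrast is the last coefficient: X beta = X T^-1 (T beta)
  # with T carrying c' in its last row; columns of X R^-1 from QR give an
  # orthonormal basis in fit order. Simpler: project out the other effects.
  XtXi <- fit$cov_unscaled
  v <- drop(XtXi %*% cvec)
  u1 <- drop(X %*% v) / sqrt(drop(crossprod(cvec, v)))  # unit-norm signal direction
  # residual-space basis: complement of col(X)
  Q <- qr.Q(fit$qr, complete = TRUE)
  RQ <- Q[, (p + 1):n, drop = FALSE]
  Yw <- fit$coefficients %*% t(X) + fit$residuals_whitened   # whitened data
  z1 <- drop(Yw %*% u1)
  Zr <- Yw %*% RQ
  list(z1 = z1, Zr = Zr, d = n - p)
}

# internal: observed and rotated moderated t for all metabolites
rotation_moderated_t <- function(fit, contrast, n_rotations) {
  ce <- contrast_effects(fit, contrast)
  d <- ce$d
  d0 <- fit$prior$d0
  s0 <- fit$prior$s0_sq
  mod_t <- function(z1, s2) {
    s2post <- if (is.infinite(d0)) rep(s0, length(s2)) else
      if (d0 == 0) s2 else (d0 * s0 + d * s2) / (d0 + d)
    z1 / sqrt(s2post)
  }
  s2_obs <- rowSums(ce$Zr^2) / d
  t_obs <- mod_t(ce$z1, s2_obs)
  tot2 <- ce$z1^2 + rowSums(ce$Zr^2)
  Z <- cbind(ce$z1, ce$Zr)                       # metabolites x (d+1)
  k <- d + 1L
  Trot <- matrix(0, n_rotations, length(ce$z1))
  for (b in seq_len(n_rotations)) {
    r <- stats::rnorm(k)
    r <- r / sqrt(sum(r^2))
    z1s <- drop(Z %*% r)
    s2s <- pmax(tot2 - z1s^2, 1e-300) / d
    Trot[b, ] <- mod_t(z1s, s2s)
  }
  colnames(Trot) <- fit$metabolite_ids
  list(t_obs = stats::setNames(t_obs, fit$metabolite_ids), t_rot = Trot)
}

#' Rotation tests for metabolite sets
#'
#' Self-contained enrichment tests on the moderated t-statistics of a
#' contrast: for each set, the observed statistic is the mean moderated t
#' over members (directional) or the mean squared moderated t (mixed
#' directionality); its null distribution comes from random rotations of the
#' residual-space representation of the data, which preserve the correlation
#' among metabolites. One shared pool of rotations serves every set, so
#' testing many sets costs little more than testing one.
#'
#' @param fit an `abundance_fit`.
#' @param sets named list of character vectors of metabolite ids.
#' @param contrast contrast name (column of the fit's contrast matrix) or a
#'   numeric contrast vector.
#' @param n_rotations number of rotations.
#' @param min_subset_size sets smaller than this (after intersecting with the
#'   fitted metabolites) are skipped.
#' @param seed integer seed for the rotations.
#' @return Data frame of class `enrichment_result`: `pathway`, `n_metabolites`,
#'   `mean_t`, `p_up`, `p_down`, `p_mixed`, `skipped`.
#' @export
rotation_set_test <- function(fit, sets, contrast = "macula_vs_periphery",
                              n_rotations = 9999L, min_subset_size = 3L,
                              seed = 1L) {
  stopifnot(inherits(fit, "abundance_fit"))
  set.seed(seed)
  rt <- rotation_moderated_t(fit, contrast, n_rotations)
  ids <- fit$metabolite_ids
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], ids)
    n <- length(members)
    if (n < min_subset_size)
      return(data.frame(pathway = nm, n_metabolites = n, mean_t = NA_real_,
                        p_up = NA_real_, p_down = NA_real_, p_mixed = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    obs_mean <- mean(rt$t_obs[members])
    obs_msq <- mean(rt$t_obs[members]^2)
    null_mean <- rowMeans(rt$t_rot[, members, drop = FALSE])
    null_msq <- rowMeans(rt$t_rot[, members, drop = FALSE]^2)
    p_up <- (1 + sum(null_mean >= obs_mean)) / (n_rotations + 1)
    p_down <- (1 + sum(null_mean <= obs_mean)) / (n_rotations + 1)
    p_mixed <- (1 + sum(null_msq >= obs_msq)) / (n_rotations + 1)
    data.frame(pathway = nm, n_metabolites = n, mean_t = obs_mean,
               p_up = p_up, p_down = p_down, p_mixed = p_mixed,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Directional calls for pathway enrichment results
#'
#' Adds Benjamini-Hochberg FDR columns (across pathways, within each
#' statistic type) and a direction call: `enriched` when the up-test is
#' significant and the down-test is not, `depleted` for the converse, `mixed`
#' when only the mixed-directionality test is significant, `none` otherwise.
#'
#' @param result an `enrichment_result`.
#' @param fdr_cutoff cutoff on the adjusted p-values.
#' @return The result with `fdr_up`, `fdr_down`, `fdr_mixed` and `call`.
#' @export
classify_direction <- function(result, fdr_cutoff = 0.05) {
  res <- result
  tested <- !res$skipped
  for (col in c("p_up", "p_down", "p_mixed")) {
    fcol <- sub("p_", "fdr_", col)
    res[[fcol]] <- NA_real_
    res[[fcol]][tested] <- stats::p.adjust(res[[col]][tested], method = "BH")
  }
  up <- !is.na(res$fdr_up) & res$fdr_up < fdr_cutoff
  dn <- !is.na(res$fdr_down) & res$fdr_down < fdr_cutoff
  mx <- !is.na(res$fdr_mixed) & res$fdr_mixed < fdr_cutoff
  call <- rep("none", nrow(res))
  call[mx & !up & !dn] <- "mixed"
  call[up & !dn] <- "enriched"
  call[dn & !up] <- "depleted"
  res$call <- ifelse(res$skipped, NA_character_, call)
  res
}

# Pathway principal-component scores --------------------------------------

#' First-principal-component pathway scores
#'
#' Summarizes each pathway by the first principal component of its member
#' metabolites' standardized abundances across samples (an "eigen-metabolite").
#' The score sign is fixed so that the majority of member loadings are
#' positive (ties resolved by the sign of the alphabetically first member's
#' loading), making "higher score" mean "higher typical member abundance". A
#' singleton pathway's score is the standardized metabolite itself.
#'
#' @param x a complete standardized `abundance_matrix`.
#' @param annotation data frame with `metabolite_id`, `family`.
#' @return List of class `pathway_scores`: `scores` (pathways x samples
#'   matrix), `explained` (PC1 variance fraction per pathway), `n_members`.
#' @export
pathway_pc_scores <- function(x, annotation) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (anyNA(x$values)) stop("pathway scores require a complete matrix")
  v <- x$values
  sds <- apply(v, 1, stats::sd)
  z <- (v - rowMeans(v)) / ifelse(sds > 0, sds, 1)
  fams <- unique(annotation$family)
  scores <- matrix(NA_real_, length(fams), ncol(v),
                   dimnames = list(fams, colnames(v)))
  explained <- stats::setNames(rep(NA_real_, length(fams)), fams)
  nmem <- stats::setNames(integer(length(fams)), fams)
  for (f in fams) {
    members <- intersect(annotation$metabolite_id[annotation$family == f],
                         rownames(z))
    nmem[f] <- length(members)
    if (length(members) == 0) next
    if (length(members) == 1) {
      scores[f, ] <- z[members, ]
      explained[f] <- 1
      next
    }
    sub <- t(z[members, , drop = FALSE])          # samples x members
    pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1]
    load <- pc$rotation[, 1]
    nsign <- sum(load > 0) - sum(load < 0)
    flip <- if (nsign != 0) sign(nsign) else {
      first <- sort(members)[1]
      s <- sign(load[first]); if (s == 0) 1 else s
    }
    scores[f, ] <- sc * flip
    explained[f] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  keep <- nmem > 0
  structure(list(scores = scores[keep, , drop = FALSE],
                 explained = explained[keep], n_members = nmem[keep]),
            class = "pathway_scores")
}

#' Differential testing of pathway PC scores
#'
#' Reuses the regional GLS fit on the pathway score matrix. With only a few
#' dozen pathways the empirical-Bayes prior is unstable, so no cross-pathway
#' variance moderation is applied by default.
#'
#' @param ps a `pathway_scores` object.
#' @param samples sample table.
#' @param rho within-subject correlation (e.g. the consensus from the
#'   metabolite-level fit); `NULL` re-estimates it from the scores.
#' @param fdr_cutoff significance cutoff.
#' @param ... passed to [fit_abundance_model()].
#' @return A `contrast_results` data frame at pathway level (the
#'   `metabolite_id` column carries pathway names).
#' @export
pathway_pc_differential <- function(ps, samples, rho = NULL,
                                    fdr_cutoff = 0.05, ...) {
  stopifnot(inherits(ps, "pathway_scores"))
  sc <- ps$scores
  keep <- apply(sc, 1, stats::sd) > 0
  mat <- standardize(abundance_matrix(sc[keep, , drop = FALSE], scale = "imputed"))
  fit <- fit_abundance_model(mat, samples, rho = rho, moderate = FALSE, ...)
  test_contrasts(fit, fdr_cutoff = fdr_cutoff)
}
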
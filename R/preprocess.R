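#' Natural-log transform of raw abundances
#'
#' Peak-area distributions are strongly right-skewed; the natural log brings
#' them close to symmetric. The missing mask is untouched. All downstream
#' effect sizes in this package are therefore natural-log units.
#'
#' @param x an `abundance_matrix` with `scale = "raw"`.
#' @return The matrix with `scale = "log"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale != "raw")
    stop("log_transform() expects a raw matrix; got scale=", x$scale)
  if (any(x$values <= 0, na.rm = TRUE))
    stop("cannot log-transform non-positive abundances")
  set_values(x, log(x$values), scale = "log")
}

#' Remove per-group median log abundance
#'
#' For every (region, batch) sample group, subtracts the median over all
#' present cells of that group's samples, so each group's global median log
#' abundance becomes zero. Subtraction on the log scale is the exact analogue
#' of dividing raw abundances by a group-level geometric median.
#'
#' @param x an `abundance_matrix` on the log scale.
#' @param samples sample table covering the matrix columns.
#' @param group_keys metadata columns defining normalization groups.
#' @return The matrix with `scale = "normalized"`.
#' @export
median_normalize <- function(x, samples, group_keys = c("region", "batch")) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!x$scale %in% c("log", "normalized", "imputed"))
    stop("median_normalize() expects log-scale (or later) values; got scale=", x$scale)
  samples <- align_samples(x, samples)
  grp <- interaction(samples[group_keys], drop = TRUE)
  v <- x$values
  for (g in levels(grp)) {
    cols <- which(grp == g)
    cells <- v[, cols, drop = FALSE]
    if (all(is.na(cells))) stop("normalization group '", g, "' has no observed values")
    v[, cols] <- cells - stats::median(cells, na.rm = TRUE)
  }
  set_values(x, v, scale = "normalized")
}

#' Filter metabolites by missingness and variance
#'
#' Drops metabolites whose missing fraction is at or above the cutoff
#' (inclusive), and metabolites whose observed values have zero variance.
#'
#' @param x an `abundance_matrix`.
#' @param missingness_cutoff inclusive missing-fraction cutoff.
#' @return List with `matrix` (filtered) and `dropped` (data frame with
#'   `metabolite_id`, `reason` in {high_missingness, zero_variance}).
#' @export
filter_metabolites <- function(x, missingness_cutoff = 0.80) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  frac <- rowMeans(is.na(v))
  high <- frac >= missingness_cutoff
  obs_var <- apply(v, 1, function(z) stats::var(z[!is.na(z)]))
  zerovar <- !high & (is.na(obs_var) | obs_var == 0)
  dropped <- data.frame(
    metabolite_id = c(rownames(v)[high], rownames(v)[zerovar]),
    reason = c(rep("high_missingness", sum(high)), rep("zero_variance", sum(zerovar))),
    stringsAsFactors = FALSE)
  keep <- !(high | zerovar)
  if (!any(keep)) stop("all metabolites dropped by filtering")
  x$values <- v[keep, , drop = FALSE]
  list(matrix = x, dropped = dropped)
}

#' Quantile normalization across samples
#'
#' Replaces each sample's sorted values by the across-sample mean of sorted
#' values at each rank, so all samples share one value distribution; ties
#' receive the mean of the reference values at their tied ranks. Delegates to
#' the standard quantile routine of the limma package (tie-averaging variant).
#' Runs after imputation: the matrix must be complete.
#'
#' @param x a complete `abundance_matrix` (scale `"imputed"`).
#' @return The matrix with `scale = "normalized"`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (anyNA(x$values))
    stop("quantile_normalize() requires a complete matrix; impute first")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  set_values(x, v, scale = "normalized")
}

#' PCA-based sample quality control
#'
#' Computes per-sample scores on the first two principal components of the
#' metabolite-standardized matrix and flags (i) samples lying more than
#' `k_outlier` robust SDs from their region centroid in the PC1/PC2 plane
#' (`pc_outlier`), and (ii) samples whose mean control-metabolite abundance
#' contradicts their region label (`control_metabolite_mismatch`): a
#' macula-labelled sample below the across-region midpoint of the control
#' signal, or a non-macula sample above it. Control metabolites are
#' macula markers (e.g. the macular pigments lutein/zeaxanthin).
#'
#' @param x a complete `abundance_matrix`.
#' @param samples sample table.
#' @param control_metabolite_ids ids of macula-marker metabolites; `NULL`
#'   skips the control check.
#' @param k_outlier robust-SD multiple for PC outlier flagging.
#' @return List of class `qc_report`: `scores` (data frame sample_id, PC1,
#'   PC2, region), `flagged` (data frame sample_id, reason), `explained`
#'   (variance fractions of PC1/PC2).
#' @export
pca_qc <- function(x, samples, control_metabolite_ids = NULL, k_outlier = 3) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (anyNA(x$values)) stop("pca_qc() requires a complete matrix")
  if (ncol(x$values) < 3) stop("pca_qc() needs at least 3 samples")
  samples <- align_samples(x, samples)
  v <- x$values
  sds <- apply(v, 1, stats::sd)
  z <- (v - rowMeans(v)) / ifelse(sds > 0, sds, 1)
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  scores <- data.frame(sample_id = colnames(v), PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                       region = samples$region, stringsAsFactors = FALSE)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]

  flagged <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (r in levels(samples$region)) {
    idx <- which(samples$region == r)
    if (length(idx) < 2) next
    cen <- c(stats::median(scores$PC1[idx]), stats::median(scores$PC2[idx]))
    rsd <- c(stats::mad(scores$PC1[idx]), stats::mad(scores$PC2[idx]))
    rsd[rsd == 0] <- stats::sd(c(scores$PC1[idx], scores$PC2[idx])) + 1e-12
    d <- sqrt(((scores$PC1[idx] - cen[1]) / rsd[1])^2 +
                ((scores$PC2[idx] - cen[2]) / rsd[2])^2)
    out <- idx[d > k_outlier * sqrt(2)]
    if (length(out))
      flagged <- rbind(flagged, data.frame(sample_id = scores$sample_id[out],
                                           reason = "pc_outlier",
                                           stringsAsFactors = FALSE))
  }

  if (!is.null(control_metabolite_ids)) {
    present <- intersect(control_metabolite_ids, rownames(v))
    if (length(present) == 0) {
      warning("control metabolites absent from the matrix; control check skipped")
    } else {
      ctrl <- colMeans(v[present, , drop = FALSE])
      is_mac <- samples$region == "macula"
      midpoint <- (mean(ctrl[is_mac]) + mean(ctrl[!is_mac])) / 2
      bad <- (is_mac & ctrl < midpoint) | (!is_mac & ctrl > midpoint)
      if (any(bad))
        flagged <- rbind(flagged, data.frame(sample_id = colnames(v)[bad],
                                             reason = "control_metabolite_mismatch",
                                             stringsAsFactors = FALSE))
    }
  }
  structure(list(scores = scores, flagged = flagged, explained = explained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, PC1 %.1f%% / PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$explained[1], 100 * x$explained[2]))
  if (nrow(x$flagged) == 0) cat("  no samples flagged\n")
  else for (i in seq_len(nrow(x$flagged)))
    cat(sprintf("  flagged %s (%s)\n", x$flagged$sample_id[i], x$flagged$reason[i]))
  invisible(x)
}
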
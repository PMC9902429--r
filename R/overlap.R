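#' Stratify pathway members by their regional retina status
#'
#' Splits each pathway's metabolites into three strata by their
#' macula-vs-periphery retina result: significantly positive =
#' `macula_enriched`, significantly negative = `macula_depleted`, otherwise
#' `not_differentiated`. Only metabolites present in the serum summary are
#' kept (exact id match after case-folding); the number dropped per pathway
#' is recorded.
#'
#' @param retina a `contrast_results` data frame containing the
#'   `macula_vs_periphery` contrast.
#' @param annotation pathway annotation (`metabolite_id`, `family`).
#' @param serum serum summary data frame (`metabolite_id`, `statistic`,
#'   `study`, ...).
#' @param fdr_cutoff significance cutoff on the retina fdr.
#' @param min_subset_size strata smaller than this are flagged `skipped`.
#' @return Data frame of class `stratified_pathways`: `pathway`, `stratum`,
#'   `n_members`, `members` (list column), `skipped`, plus attribute
#'   `n_dropped` (metabolites absent from the serum table).
#' @export
stratify_pathways <- function(retina, annotation, serum, fdr_cutoff = 0.05,
                              min_subset_size = 3L) {
  mvp <- retina[retina$contrast == "macula_vs_periphery", , drop = FALSE]
  if (!nrow(mvp)) stop("retina results lack the macula_vs_periphery contrast")
  key_serum <- tolower(unique(serum$metabolite_id))
  mvp$key <- tolower(mvp$metabolite_id)
  in_serum <- mvp$key %in% key_serum
  n_dropped <- sum(!in_serum)
  mvp <- mvp[in_serum, , drop = FALSE]
  if (!nrow(mvp)) stop("no metabolites overlap between retina and serum tables")
  stratum <- ifelse(mvp$fdr < fdr_cutoff & mvp$logFC > 0, "macula_enriched",
             ifelse(mvp$fdr < fdr_cutoff & mvp$logFC < 0, "macula_depleted",
                    "not_differentiated"))
  ann <- annotation
  ann$key <- tolower(ann$metabolite_id)
  mvp$family <- ann$family[match(mvp$key, ann$key)]
  mvp$stratum <- stratum
  mvp <- mvp[!is.na(mvp$family), , drop = FALSE]
  strata_levels <- c("macula_enriched", "not_differentiated", "macula_depleted")
  rows <- list()
  for (f in unique(mvp$family)) for (s in strata_levels) {
    members <- mvp$metabolite_id[mvp$family == f & mvp$stratum == s]
    if (!length(members)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = f, stratum = s, n_members = length(members),
      skipped = length(members) < min_subset_size, stringsAsFactors = FALSE)
    rows[[length(rows)]]$members <- list(members)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("stratified_pathways", "data.frame")
  out
}

#' Enrichment of region strata in a disease serum study
#'
#' Tests each (pathway, stratum) group of metabolites for a coordinated shift
#' in the serum case-vs-control statistics. When a fitted serum model is
#' supplied, the null distribution comes from residual-space rotations
#' (preserving inter-metabolite correlation); with summary statistics only,
#' the null is built by resampling member-sized subsets from the study's full
#' statistic vector — a documented fallback that ignores inter-metabolite
#' correlation.
#'
#' @param strata output of [stratify_pathways()].
#' @param serum serum summary data frame for a single study (`metabolite_id`,
#'   `statistic`, `study`).
#' @param mode `"fdr"` (flag at BH FDR < cutoff) or `"nominal"` (flag at
#'   unadjusted p < cutoff).
#' @param serum_fit optional `abundance_fit` of the serum study, enabling the
#'   rotation null.
#' @param serum_contrast contrast name/vector for the rotation null.
#' @param n_null number of rotations or resampling draws.
#' @param cutoff significance cutoff.
#' @param seed integer seed.
#' @return Data frame of class `overlap_result`: `pathway`, `stratum`, `n`,
#'   `mean_statistic`, `p_up`, `p_down`, `p_mixed`, `fdr_*` (mode = fdr),
#'   `significant`, `direction`, `study`, `null_method`.
#' @export
overlap_enrichment <- function(strata, serum, mode = c("fdr", "nominal"),
                               serum_fit = NULL, serum_contrast = "case_vs_control",
                               n_null = 9999L, cutoff = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  study <- unique(serum$study)
  if (length(study) != 1)
    stop("overlap_enrichment() expects a single study; got: ",
         paste(study, collapse = ", "))
  tested <- strata[!strata$skipped, , drop = FALSE]
  if (!nrow(tested)) stop("no testable strata")
  set.seed(seed)
  stat <- stats::setNames(serum$statistic, tolower(serum$metabolite_id))
  if (!is.null(serum_fit)) {
    rt <- rotation_moderated_t(serum_fit, serum_contrast, n_null)
    null_t <- rt$t_rot
    colnames(null_t) <- tolower(colnames(null_t))
    obs_t <- rt$t_obs
    names(obs_t) <- tolower(names(obs_t))
    null_method <- "rotation"
  } else {
    null_method <- "resampling"
  }
  rows <- lapply(seq_len(nrow(tested)), function(i) {
    members <- tolower(tested$members[[i]])
    members <- members[members %in% names(stat)]
    n <- length(members)
    obs <- stat[members]
    obs_mean <- mean(obs); obs_msq <- mean(obs^2)
    if (!is.null(serum_fit) && all(members %in% names(obs_t))) {
      null_mean <- rowMeans(null_t[, members, drop = FALSE])
      null_msq <- rowMeans(null_t[, members, drop = FALSE]^2)
      om <- mean(obs_t[members]); omsq <- mean(obs_t[members]^2)
    } else {
      draws <- matrix(sample(stat, n * n_null, replace = TRUE), n_null, n)
      null_mean <- rowMeans(draws)
      null_msq <- rowMeans(draws^2)
      om <- obs_mean; omsq <- obs_msq
    }
    p_up <- (1 + sum(null_mean >= om)) / (n_null + 1)
    p_down <- (1 + sum(null_mean <= om)) / (n_null + 1)
    p_mixed <- (1 + sum(null_msq >= omsq)) / (n_null + 1)
    data.frame(pathway = tested$pathway[i], stratum = tested$stratum[i],
               n = n, mean_statistic = obs_mean,
               p_up = p_up, p_down = p_down, p_mixed = p_mixed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (col in c("p_up", "p_down", "p_mixed"))
    out[[sub("p_", "fdr_", col)]] <- stats::p.adjust(out[[col]], method = "BH")
  pmin2 <- pmin(out$p_up, out$p_down)
  if (mode == "fdr") {
    sig_dir <- pmin(out$fdr_up, out$fdr_down) < cutoff
    sig_mix <- out$fdr_mixed < cutoff
  } else {
    sig_dir <- pmin2 < cutoff
    sig_mix <- out$p_mixed < cutoff
  }
  out$significant <- sig_dir | sig_mix
  out$direction <- ifelse(!out$significant, "none",
                   ifelse(sig_dir & out$p_up <= out$p_down, "up",
                   ifelse(sig_dir, "down", "mixed")))
  out$study <- study
  out$null_method <- null_method
  out$mode <- mode
  class(out) <- c("overlap_result", "data.frame")
  out
}

#' Long-format overlap report
#'
#' Combines stratified overlap-enrichment results for one or more studies
#' into a single long-format table (pathway x stratum x study) ready to be
#' written with [write_results()]. Skipped strata are omitted.
#'
#' @param ... one or more `overlap_result` data frames.
#' @return Data frame with columns `pathway`, `stratum`, `study`, `n`,
#'   `mean_statistic`, `p_up`, `p_down`, `p_mixed`, `fdr_up`, `fdr_down`,
#'   `fdr_mixed`, `significant`, `direction`, `null_method`, `mode`.
#' @export
overlap_report <- function(...) {
  parts <- list(...)
  if (!length(parts)) stop("no overlap results supplied")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  cols <- c("pathway", "stratum", "study", "n", "mean_statistic", "p_up",
            "p_down", "p_mixed", "fdr_up", "fdr_down", "fdr_mixed",
            "significant", "direction", "null_method", "mode")
  out[cols]
}

#' Serum summary table from a fitted case/control model
#'
#' Convenience bridge between the differential-abundance fit of a serum
#' study and the overlap stage's summary-table input.
#'
#' @param fit an `abundance_fit` of a case/control design.
#' @param contrast contrast name.
#' @param study study label (e.g. `"MacTel"`, `"AMD-CNV"`).
#' @return Data frame with `metabolite_id`, `logFC`, `statistic`, `p`, `fdr`,
#'   `study`.
#' @export
serum_summary_from_fit <- function(fit, contrast = "case_vs_control",
                                   study = "study") {
  res <- test_contrasts(fit)
  res <- res[res$contrast == contrast, , drop = FALSE]
  data.frame(metabolite_id = res$metabolite_id, logFC = res$logFC,
             statistic = res$t, p = res$p, fdr = res$fdr, study = study,
             stringsAsFactors = FALSE)
}
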
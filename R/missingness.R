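#' Find the two auxiliary metabolites for a focal metabolite
#'
#' Candidates are all other metabolites sharing at least `min_overlap` samples
#' where both the focal and the candidate are observed. Candidates are ranked
#' by signed pairwise-complete Pearson correlation (descending), ties broken
#' by larger overlap, then lexicographic id. Signed (not absolute) ranking is
#' deliberate: the mechanism test below asks whether the auxiliaries are
#' *lower* when the focal metabolite is missing, which presumes positively
#' co-varying auxiliaries.
#'
#' @param x an `abundance_matrix` (log or normalized scale).
#' @param metabolite_id focal metabolite (must have >= 1 missing value).
#' @param min_overlap minimum joint-observation count.
#' @return A list (`metabolite_id`, `aux1_id`, `aux2_id`, `r1`, `r2`, `n1`,
#'   `n2`) or `NULL` when fewer than two valid candidates exist.
#' @export
find_auxiliaries <- function(x, metabolite_id, min_overlap = 3L) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  if (!metabolite_id %in% rownames(v)) stop("unknown metabolite: ", metabolite_id)
  focal <- v[metabolite_id, ]
  if (!anyNA(focal)) stop("focal metabolite has no missing values")
  others <- setdiff(rownames(v), metabolite_id)
  stats_list <- lapply(others, function(id) {
    both <- !is.na(focal) & !is.na(v[id, ])
    n <- sum(both)
    if (n < min_overlap) return(NULL)
    r <- suppressWarnings(stats::cor(focal[both], v[id, both]))
    if (is.na(r)) return(NULL)
    list(id = id, r = r, n = n)
  })
  stats_list <- Filter(Negate(is.null), stats_list)
  if (length(stats_list) < 2) return(NULL)
  ids <- vapply(stats_list, `[[`, "", "id")
  rs <- vapply(stats_list, `[[`, 0, "r")
  ns <- vapply(stats_list, `[[`, 0, "n")
  ord <- order(-rs, -ns, ids)
  list(metabolite_id = metabolite_id,
       aux1_id = ids[ord[1]], aux2_id = ids[ord[2]],
       r1 = rs[ord[1]], r2 = rs[ord[2]], n1 = ns[ord[1]], n2 = ns[ord[2]])
}

#' Classify the missingness mechanism of one metabolite
#'
#' For each auxiliary, a one-sided Welch two-sample t-test compares the
#' auxiliary's observed values at samples where the focal metabolite is
#' missing against samples where it is present, alternative "lower when focal
#' missing". If either auxiliary is significantly lower (p < alpha) the focal
#' metabolite is labelled MNAR (left-censored); otherwise MAR. Metabolites
#' with fewer than 3 missing or fewer than 3 observed values, or without
#' usable auxiliaries, are labelled UNTESTABLE_MAR and treated as MAR
#' downstream.
#'
#' @param x an `abundance_matrix`.
#' @param metabolite_id focal metabolite.
#' @param pair auxiliary pair from [find_auxiliaries()] (or `NULL`).
#' @param alpha per-test significance level.
#' @return List with `mechanism` (`"MAR"`, `"MNAR"` or `"UNTESTABLE_MAR"`),
#'   `p_aux1`, `p_aux2` (NA when not computed).
#' @export
classify_mechanism <- function(x, metabolite_id, pair, alpha = 0.05) {
  v <- x$values
  focal <- v[metabolite_id, ]
  n_miss <- sum(is.na(focal))
  n_obs <- sum(!is.na(focal))
  out <- list(mechanism = "UNTESTABLE_MAR", p_aux1 = NA_real_, p_aux2 = NA_real_)
  if (is.null(pair) || n_miss < 3 || n_obs < 3) return(out)
  pvals <- c(NA_real_, NA_real_)
  for (k in 1:2) {
    aux <- v[pair[[c("aux1_id", "aux2_id")[k]]], ]
    a_miss <- aux[is.na(focal) & !is.na(aux)]
    a_obs <- aux[!is.na(focal) & !is.na(aux)]
    if (length(a_miss) < 2 || length(a_obs) < 2) next
    pvals[k] <- tryCatch(
      stats::t.test(a_miss, a_obs, alternative = "less", var.equal = FALSE)$p.value,
      error = function(e) NA_real_)
  }
  out$p_aux1 <- pvals[1]; out$p_aux2 <- pvals[2]
  if (all(is.na(pvals))) return(out)
  out$mechanism <- if (min(pvals, na.rm = TRUE) < alpha) "MNAR" else "MAR"
  out
}

#' Missingness-mechanism report for all incomplete metabolites
#'
#' Runs the auxiliary search and mechanism test for every metabolite with at
#' least one missing value. Correlations and overlaps are computed once for
#' the whole matrix, so the report scales to thousands of metabolites.
#'
#' @param x an `abundance_matrix` on the (median-)normalized log scale.
#' @param config a [run_config()] supplying `min_overlap_for_correlation` and
#'   `aux_test_alpha`.
#' @return Data frame of class `missingness_report`, one row per incomplete
#'   metabolite: ids and correlations of the auxiliary pair, the two one-sided
#'   Welch p-values, and `mechanism`.
#' @export
missingness_report <- function(x, config = run_config()) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  incomplete <- rownames(v)[rowSums(is.na(v)) > 0]
  obs <- !is.na(v)
  overlap <- tcrossprod(obs * 1)                      # joint-observation counts
  cors <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  min_ov <- config$min_overlap_for_correlation
  rows <- lapply(incomplete, function(id) {
    r <- cors[id, ]; nv <- overlap[id, ]
    r[names(r) == id] <- NA
    r[nv < min_ov] <- NA
    ok <- which(!is.na(r))
    pair <- NULL
    if (length(ok) >= 2) {
      ord <- ok[order(-r[ok], -nv[ok], names(r)[ok])]
      pair <- list(metabolite_id = id,
                   aux1_id = names(r)[ord[1]], aux2_id = names(r)[ord[2]],
                   r1 = r[ord[1]], r2 = r[ord[2]],
                   n1 = nv[ord[1]], n2 = nv[ord[2]])
    }
    cls <- classify_mechanism(x, id, pair, alpha = config$aux_test_alpha)
    data.frame(metabolite_id = id,
               missing_count = sum(is.na(v[id, ])),
               missing_fraction = mean(is.na(v[id, ])),
               aux1_id = if (is.null(pair)) NA_character_ else pair$aux1_id,
               aux2_id = if (is.null(pair)) NA_character_ else pair$aux2_id,
               r1 = if (is.null(pair)) NA_real_ else unname(pair$r1),
               r2 = if (is.null(pair)) NA_real_ else unname(pair$r2),
               n1 = if (is.null(pair)) NA_integer_ else unname(pair$n1),
               n2 = if (is.null(pair)) NA_integer_ else unname(pair$n2),
               p_aux1 = cls$p_aux1, p_aux2 = cls$p_aux2,
               mechanism = cls$mechanism,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite_id = character(0), missing_count = integer(0),
               missing_fraction = numeric(0), aux1_id = character(0),
               aux2_id = character(0), r1 = numeric(0), r2 = numeric(0),
               n1 = integer(0), n2 = integer(0), p_aux1 = numeric(0),
               p_aux2 = numeric(0), mechanism = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("missingness_report", "data.frame")
  out
}

#' @export
print.missingness_report <- function(x, ...) {
  tab <- table(factor(x$mechanism, c("MAR", "MNAR", "UNTESTABLE_MAR")))
  cat(sprintf("missingness_report: %d incomplete metabolites (MAR %d, MNAR %d, untestable %d)\n",
              nrow(x), tab["MAR"], tab["MNAR"], tab["UNTESTABLE_MAR"]))
  invisible(x)
}
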
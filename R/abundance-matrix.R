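#' Metabolite abundance matrix
#'
#' The central data container of the package: a metabolites-by-samples matrix
#' of peak areas (or their transformed values) together with a scale tag that
#' records where the matrix sits in the preprocessing pipeline. Missing cells
#' are encoded as `NA`; the missing mask is therefore `is.na(values(x))`.
#'
#' @param values numeric matrix, metabolites in rows, samples in columns, with
#'   unique non-empty dimnames. `NA` marks a missing cell.
#' @param scale one of `"raw"`, `"log"`, `"normalized"`, `"imputed"`. Raw
#'   values must be strictly positive where present; an `"imputed"` matrix
#'   must be complete.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("raw", "log", "normalized", "imputed")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (metabolites x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry metabolite row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate metabolite IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw abundances must be strictly positive where present")
  if (scale == "imputed" && anyNA(values))
    stop("an imputed matrix must not contain missing values")
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
values <- function(x, ...) UseMethod("values")

#' @export
values.abundance_matrix <- function(x, ...) x$values

#' Missing-cell mask of an abundance matrix
#'
#' @param x an `abundance_matrix`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  is.na(x$values)
}

#' @export
abundance_scale <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  x$scale
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
dimnames.abundance_matrix <- function(x) dimnames(x$values)

metabolite_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' @export
print.abundance_matrix <- function(x, ...) {
  d <- dim(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("abundance_matrix: %d metabolites x %d samples [scale=%s]\n",
              d[1], d[2], x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss, 100 * nmiss / prod(d)))
  invisible(x)
}

# internal: replace the value matrix, optionally retagging the scale
set_values <- function(x, v, scale = x$scale) {
  x$values <- v
  x$scale <- scale
  x
}

#' Validate a sample metadata table
#'
#' Checks the design metadata that accompanies an abundance matrix: one row
#' per sample with subject, eye, region (macula / temporal / periphery), sex,
#' age and preparation batch. Region and eye labels are case-normalized.
#'
#' @param df data frame with columns `sample_id`, `subject_id`, `eye`,
#'   `region`, `sex`, `age`, `batch`.
#' @return The validated data frame (factors for region/sex, character ids).
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "subject_id", "eye", "region", "sex", "age", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample table is missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  regions <- c("macula", "temporal", "periphery")
  reg <- tolower(as.character(df$region))
  bad <- setdiff(unique(reg), regions)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(regions, collapse = ", "))
  df$region <- factor(reg, levels = regions)
  eyes <- c("left", "right", "unknown")
  eye <- tolower(as.character(df$eye))
  bad <- setdiff(unique(eye), eyes)
  if (length(bad))
    stop("unknown eye label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(eyes, collapse = ", "))
  df$eye <- factor(eye, levels = eyes)
  sex <- toupper(as.character(df$sex))
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad))
    stop("unknown sex label(s): ", paste(bad, collapse = ", "), "; allowed: F, M")
  df$sex <- factor(sex, levels = c("F", "M"))
  df$age <- as.numeric(df$age)
  df$batch <- factor(as.character(df$batch))
  df
}

# internal: align a sample table to the columns of an abundance matrix
align_samples <- function(mat, samples) {
  sid <- sample_ids(mat)
  if (!all(sid %in% samples$sample_id))
    stop("samples missing from the sample table: ",
         paste(setdiff(sid, samples$sample_id), collapse = ", "))
  samples[match(sid, samples$sample_id), , drop = FALSE]
}

#' Run configuration
#'
#' Bundles the tuning constants shared across pipeline stages.
#'
#' @param seed integer seed consumed by every randomized stage.
#' @param fdr_cutoff Benjamini-Hochberg significance cutoff.
#' @param missingness_cutoff metabolites with a missing fraction at or above
#'   this value are dropped.
#' @param min_overlap_for_correlation minimum number of jointly observed
#'   samples for an auxiliary-metabolite correlation.
#' @param aux_test_alpha per-test alpha of the one-sided Welch tests used by
#'   the missingness-mechanism classifier.
#' @param n_rotations number of random rotations for set enrichment tests.
#' @param min_subset_size smallest pathway (or stratum) that is tested.
#' @param control_metabolite_ids optional ids of macula-marker control
#'   metabolites used by the QC stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       fdr_cutoff = 0.05,
                       missingness_cutoff = 0.80,
                       min_overlap_for_correlation = 3L,
                       aux_test_alpha = 0.05,
                       n_rotations = 9999L,
                       min_subset_size = 3L,
                       control_metabolite_ids = NULL) {
  props <- c(fdr_cutoff = fdr_cutoff, missingness_cutoff = missingness_cutoff,
             aux_test_alpha = aux_test_alpha)
  if (any(props <= 0 | props >= 1))
    stop("fdr_cutoff, missingness_cutoff and aux_test_alpha must lie in (0, 1)")
  counts <- c(min_overlap_for_correlation, n_rotations, min_subset_size)
  if (any(counts < 1 | counts != round(counts)))
    stop("count parameters must be positive integers")
  structure(list(seed = as.integer(seed), fdr_cutoff = fdr_cutoff,
                 missingness_cutoff = missingness_cutoff,
                 min_overlap_for_correlation = as.integer(min_overlap_for_correlation),
                 aux_test_alpha = aux_test_alpha,
                 n_rotations = as.integer(n_rotations),
                 min_subset_size = as.integer(min_subset_size),
                 control_metabolite_ids = control_metabolite_ids),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path path to a YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}
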
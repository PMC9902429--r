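#' Read a metabolite abundance table
#'
#' Reads a TSV/CSV export with metabolite IDs in the first column and one
#' column per sample. Blank, `NA` and `NaN` cells are treated as missing;
#' zeros are values, not missing. The table must be metabolites-in-rows: a
#' header whose first field is a sample-like id (or a table far wider than
#' tall with sample-count rows) is not silently transposed but rejected by
#' the ID checks below.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return An [abundance_matrix()] with `scale = "raw"`.
#' @export
read_abundance_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("abundance table needs an ID column plus >=1 sample column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate metabolite IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  snames <- colnames(raw)[-1]
  if (anyDuplicated(snames))
    stop("duplicate sample IDs: ",
         paste(unique(snames[duplicated(snames)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(snames),
                 dimnames = list(ids, snames))
  for (j in seq_along(snames)) {
    cell <- trimws(raw[[j + 1L]])
    blank <- cell == "" | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at metabolite '%s', sample '%s': '%s'",
                   ids[bad[1]], snames[j], cell[bad[1]]))
    neg <- which(!blank & num <= 0)
    if (length(neg))
      stop(sprintf("non-positive raw abundance at metabolite '%s', sample '%s'",
                   ids[neg[1]], snames[j]))
    num[blank] <- NA_real_
    vals[, j] <- num
  }
  abundance_matrix(vals, scale = "raw")
}

#' Read a sample metadata table
#'
#' @param path path to a delimited text file with columns `sample_id`,
#'   `subject_id`, `eye`, `region`, `sex`, `age`, `batch`.
#' @param sep field separator.
#' @return A validated sample table (see [sample_table()]).
#' @export
read_sample_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  sample_table(df)
}

#' Read a pathway annotation table
#'
#' @param path delimited file with columns `metabolite_id`, `family` and
#'   optionally `super_family`.
#' @param sep field separator.
#' @return Data frame with one row per metabolite.
#' @export
read_pathway_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  req <- c("metabolite_id", "family")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$metabolite_id))
    stop("a metabolite maps to more than one family: ",
         paste(unique(df$metabolite_id[duplicated(df$metabolite_id)]), collapse = ", "))
  df
}

#' Read an external serum differential-abundance summary table
#'
#' @param path delimited file with columns `metabolite_id`, `logFC`,
#'   `statistic`, `p`, `fdr`, `study`.
#' @param sep field separator.
#' @return Data frame, one row per metabolite per study.
#' @export
read_serum_summary <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  req <- c("metabolite_id", "logFC", "statistic", "p", "fdr", "study")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("serum summary is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("metabolite_id", "study")]))
    stop("serum summary has duplicate (metabolite, study) rows")
  if (any(df$p <= 0 | df$p > 1)) stop("serum p-values must lie in (0, 1]")
  df
}

#' Write a pipeline product to TSV with a JSON run log
#'
#' Writes any tabular pipeline product (an `abundance_matrix`, a sample table,
#' contrast results, enrichment or overlap tables) as a TSV with full numeric
#' precision, and a `<path>.log.json` run log alongside recording the seed and
#' configuration, package version and table shape.
#'
#' @param x the object to write.
#' @param path output TSV path.
#' @param config optional [run_config()] recorded in the run log.
#' @export
write_results <- function(x, path, config = NULL) {
  if (inherits(x, "abundance_matrix")) {
    df <- data.frame(metabolite_id = rownames(x$values),
                     x$values, check.names = FALSE, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    stop("write_results() supports abundance matrices and data frames, not ",
         paste(class(x), collapse = "/"))
  }
  ok <- tryCatch({
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  log <- list(
    written = basename(path),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("regiomet")),
    r_version = as.character(getRversion()),
    n_rows = nrow(df), n_cols = ncol(df)
  )
  if (!is.null(config)) log$config <- unclass(config)
  jsonlite::write_json(log, paste0(path, ".log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(ok)
}

#' Write an abundance matrix (round-trip safe)
#'
#' Convenience wrapper over [write_results()] whose output feeds back through
#' [read_abundance_table()] with values preserved to at least 1e-9 and the
#' missing mask preserved exactly (missing cells are written as blank).
#'
#' @param x an `abundance_matrix`.
#' @param path output TSV path.
#' @param config optional run configuration for the run log.
#' @export
write_abundance_table <- function(x, path, config = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  chr <- matrix(sprintf("%.12g", v), nrow = nrow(v), dimnames = dimnames(v))
  chr[is.na(v)] <- ""
  df <- data.frame(metabolite_id = rownames(v), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- list(written = basename(path),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("regiomet")),
              scale = x$scale, n_rows = nrow(v), n_cols = ncol(v))
  if (!is.null(config)) log$config <- unclass(config)
  jsonlite::write_json(log, paste0(path, ".log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(TRUE)
}
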
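#' Significance/direction signature of the three region contrasts
#'
#' For one metabolite (or pathway), reduces its three contrast results
#' (macula-temporal, temporal-periphery, macula-periphery) to a signature of
#' signs: `+` or `-` for a significant contrast (sign of the log-fold
#' change), `0` for a non-significant one.
#'
#' @param results a `contrast_results` data frame.
#' @param id the metabolite (or pathway) identifier.
#' @param fdr_cutoff significance cutoff on the `fdr` column.
#' @return Character vector of length 3 named `macula_vs_temporal`,
#'   `temporal_vs_periphery`, `macula_vs_periphery` with values in
#'   `{"+", "-", "0"}`.
#' @export
signature_from_results <- function(results, id, fdr_cutoff = 0.05) {
  need <- c("macula_vs_temporal", "temporal_vs_periphery", "macula_vs_periphery")
  rows <- results[results$metabolite_id == id, , drop = FALSE]
  miss <- setdiff(need, rows$contrast)
  if (length(miss))
    stop("missing contrast(s) for '", id, "': ", paste(miss, collapse = ", "))
  sig <- vapply(need, function(ct) {
    r <- rows[rows$contrast == ct, ][1, ]
    if (r$fdr < fdr_cutoff) { if (r$logFC > 0) "+" else "-" } else "0"
  }, "")
  sig
}

# the rule table: signature (MvT, TvP, MvP) -> spatial pattern cluster.
# "any" in the MvP slot matches +, - and 0. Exposed via pattern_rules() so a
# user can swap in an alternative mapping.
default_pattern_rules <- function() {
  data.frame(
    mvt = c("+", "0", "+", "0", "-", "0", "0", "-", "-", "+"),
    tvp = c("+", "0", "0", "+", "-", "0", "-", "0", "+", "-"),
    mvp = c("+", "+", "+", "+", "-", "-", "-", "-", "any", "any"),
    cluster = c("steep_enrichment", "shallow_enrichment", "macula_enriched",
                "periphery_depleted", "steep_depletion", "shallow_depletion",
                "periphery_enriched", "macula_depleted", "temporal_enriched",
                "temporal_depleted"),
    stringsAsFactors = FALSE)
}

#' Spatial pattern cluster rule table
#'
#' Returns (or loads from YAML) the mapping from contrast signatures to the
#' ten named spatial pattern clusters. Each rule gives the required sign of
#' macula-temporal (`mvt`), temporal-periphery (`tvp`) and macula-periphery
#' (`mvp`); `"any"` is a wildcard. Signatures matching no rule are
#' `unclassified`.
#'
#' @param path optional YAML file with a list of rules (`mvt`, `tvp`, `mvp`,
#'   `cluster`) overriding the built-in table.
#' @return Data frame of rules.
#' @export
pattern_rules <- function(path = NULL) {
  if (is.null(path)) return(default_pattern_rules())
  y <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(y, as.data.frame, stringsAsFactors = FALSE))
  req <- c("mvt", "tvp", "mvp", "cluster")
  if (!all(req %in% names(df))) stop("pattern rule file needs fields: ",
                                     paste(req, collapse = ", "))
  df[req]
}

#' Assign a spatial pattern cluster from a signature
#'
#' Total and deterministic over the 27 possible signatures: exactly ten named
#' clusters are reachable, every remaining (internally contradictory)
#' signature maps to `unclassified` rather than being forced into a nearest
#' cluster.
#'
#' @param sig signature from [signature_from_results()] (length-3 character
#'   vector in `{"+","-","0"}`, order macula-temporal, temporal-periphery,
#'   macula-periphery).
#' @param rules rule table from [pattern_rules()].
#' @return A single cluster label.
#' @export
assign_pattern <- function(sig, rules = pattern_rules()) {
  if (length(sig) != 3 || !all(sig %in% c("+", "-", "0")))
    stop("signature must be three values in {+, -, 0}")
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if ((r$mvt == "any" || r$mvt == sig[1]) &&
        (r$tvp == "any" || r$tvp == sig[2]) &&
        (r$mvp == "any" || r$mvp == sig[3]))
      return(r$cluster)
  }
  "unclassified"
}

#' Pattern-cluster assignments for a full results table
#'
#' @param results a `contrast_results` data frame with all three region
#'   contrasts.
#' @param fdr_cutoff significance cutoff.
#' @param rules rule table.
#' @return Data frame: `metabolite_id`, `mvt`, `tvp`, `mvp`, `cluster`.
#' @export
assign_patterns <- function(results, fdr_cutoff = 0.05, rules = pattern_rules()) {
  ids <- unique(results$metabolite_id)
  sigs <- t(vapply(ids, function(id)
    signature_from_results(results, id, fdr_cutoff), character(3)))
  data.frame(metabolite_id = ids,
             mvt = sigs[, 1], tvp = sigs[, 2], mvp = sigs[, 3],
             cluster = apply(sigs, 1, assign_pattern, rules = rules),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize pattern-cluster assignments
#'
#' @param assignments output of [assign_patterns()].
#' @param annotation optional pathway annotation; when given, a
#'   pathway-by-cluster table is added (each pathway listed under the cluster
#'   holding the majority of its classified members).
#' @return List with `counts` (named integer vector over all cluster labels)
#'   and, if annotation given, `pathway_clusters` (data frame `family`,
#'   `cluster`, `n_members`).
#' @export
cluster_summary <- function(assignments, annotation = NULL) {
  labels <- c(default_pattern_rules()$cluster, "unclassified")
  counts <- table(factor(assignments$cluster, levels = labels))
  out <- list(counts = stats::setNames(as.integer(counts), names(counts)))
  if (!is.null(annotation)) {
    merged <- merge(assignments, annotation, by = "metabolite_id")
    rows <- lapply(split(merged, merged$family), function(g) {
      cl <- g$cluster[g$cluster != "unclassified"]
      top <- if (length(cl)) names(sort(table(cl), decreasing = TRUE))[1] else "unclassified"
      data.frame(family = g$family[1], cluster = top, n_members = nrow(g),
                 stringsAsFactors = FALSE)
    })
    out$pathway_clusters <- do.call(rbind, rows)
    rownames(out$pathway_clusters) <- NULL
  }
  out
}
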
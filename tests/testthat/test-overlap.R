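# small retina-results + serum fixtures built by hand
make_retina <- function(ids, fdr, lfc) {
  data.frame(metabolite_id = ids, contrast = "macula_vs_periphery",
             logFC = lfc, t = lfc, p = fdr, fdr = fdr,
             significant = fdr < 0.05, stringsAsFactors = FALSE)
}

test_that("strata partition each pathway's serum-overlapping members", {
  ids <- sprintf("M%d", 1:6)
  retina <- make_retina(ids, fdr = c(0.01, 0.01, 0.5, 0.5, 0.01, 0.5),
                        lfc = c(2, -2, 0.1, 0.2, 1.5, -0.1))
  ann <- data.frame(metabolite_id = ids, family = rep(c("A", "B"), each = 3),
                    stringsAsFactors = FALSE)
  serum <- data.frame(metabolite_id = ids[1:5], logFC = rnorm(5),
                      statistic = rnorm(5), p = runif(5), fdr = runif(5),
                      study = "S", stringsAsFactors = FALSE)
  strata <- stratify_pathways(retina, ann, serum, min_subset_size = 1)
  # pathway A: M1 enriched, M2 depleted, M3 not differentiated
  a <- strata[strata$pathway == "A", ]
  expect_setequal(a$stratum, c("macula_enriched", "macula_depleted",
                               "not_differentiated"))
  expect_equal(sum(a$n_members), 3L)
  # M6 absent from serum: dropped and counted
  expect_equal(attr(strata, "n_dropped"), 1L)
  b <- strata[strata$pathway == "B", ]
  expect_equal(sum(b$n_members), 2L)
  # conservation: no metabolite appears in two strata
  all_members <- unlist(strata$members)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("a uniformly depleted stratum is flagged by the resampling null", {
  set.seed(71)
  ids <- sprintf("M%03d", 1:200)
  stat <- rnorm(200)
  members <- ids[1:6]
  stat[1:6] <- -3 - abs(rnorm(6, 0, 0.3))     # all <= -3
  serum <- data.frame(metabolite_id = ids, logFC = stat, statistic = stat,
                      p = runif(200, 0.01, 1), fdr = runif(200, 0.05, 1),
                      study = "MacTel", stringsAsFactors = FALSE)
  retina <- make_retina(ids, fdr = ifelse(ids %in% members, 0.01, 0.5),
                        lfc = rep(1, 200))
  ann <- data.frame(metabolite_id = ids,
                    family = rep(sprintf("fam%02d", 1:20), each = 10),
                    stringsAsFactors = FALSE)
  strata <- stratify_pathways(retina, ann, serum)
  ov <- overlap_enrichment(strata, serum, mode = "fdr", n_null = 4999, seed = 5)
  hit <- ov[ov$pathway == "fam01" & ov$stratum == "macula_enriched", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$p_down, 0.01)
  expect_equal(hit$null_method, "resampling")
})

test_that("null strata give roughly uniform p-values under resampling", {
  set.seed(72)
  reps <- 200
  pvals <- replicate(reps, {
    ids <- sprintf("M%03d", 1:100)
    stat <- rnorm(100)
    serum <- data.frame(metabolite_id = ids, logFC = stat, statistic = stat,
                        p = runif(100), fdr = runif(100), study = "S",
                        stringsAsFactors = FALSE)
    retina <- make_retina(ids, fdr = rep(0.5, 100), lfc = rep(0.1, 100))
    ann <- data.frame(metabolite_id = ids,
                      family = rep(sprintf("fam%02d", 1:10), each = 10),
                      stringsAsFactors = FALSE)
    strata <- stratify_pathways(retina, ann, serum)
    ov <- overlap_enrichment(strata, serum, n_null = 199,
                             seed = sample.int(1e6, 1))
    ov$p_up[ov$pathway == "fam01"]
  })
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
  expect_lt(abs(mean(pvals <= 0.1) - 0.1), 0.06)
})

test_that("nominal mode thresholds on unadjusted p regardless of FDR", {
  ids <- sprintf("M%02d", 1:30)
  set.seed(73)
  stat <- rnorm(30); stat[1:5] <- stat[1:5] + 2.2
  serum <- data.frame(metabolite_id = ids, logFC = stat, statistic = stat,
                      p = runif(30), fdr = runif(30), study = "AMD-CNV",
                      stringsAsFactors = FALSE)
  retina <- make_retina(ids, fdr = ifelse(ids %in% ids[1:5], 0.01, 0.5),
                        lfc = rep(1, 30))
  ann <- data.frame(metabolite_id = ids, family = "fam", stringsAsFactors = FALSE)
  strata <- stratify_pathways(retina, ann, serum)
  nom <- overlap_enrichment(strata, serum, mode = "nominal", n_null = 999, seed = 2)
  fdrm <- overlap_enrichment(strata, serum, mode = "fdr", n_null = 999, seed = 2)
  expect_identical(nom$significant,
                   (pmin(nom$p_up, nom$p_down) < 0.05) | (nom$p_mixed < 0.05))
  expect_identical(fdrm$significant,
                   (pmin(fdrm$fdr_up, fdrm$fdr_down) < 0.05) | (fdrm$fdr_mixed < 0.05))
})

test_that("the long-format report has one row per tested pathway-stratum-study", {
  ids <- sprintf("M%02d", 1:12)
  set.seed(74)
  serum <- data.frame(metabolite_id = ids, logFC = rnorm(12), statistic = rnorm(12),
                      p = runif(12), fdr = runif(12), study = "S1",
                      stringsAsFactors = FALSE)
  retina <- make_retina(ids, fdr = rep(c(0.01, 0.5), 6),
                        lfc = rep(1, 12))
  ann <- data.frame(metabolite_id = ids, family = rep(c("A", "B"), each = 6),
                    stringsAsFactors = FALSE)
  strata <- stratify_pathways(retina, ann, serum)
  ov <- overlap_enrichment(strata, serum, n_null = 99, seed = 1)
  rep1 <- overlap_report(ov)
  expect_lte(nrow(rep1), 6L)
  expect_true(all(c("pathway", "stratum", "study", "significant") %in% names(rep1)))
})

test_that("zero overlap between retina and serum is a hard error", {
  retina <- make_retina(c("A1", "A2", "A3"), fdr = rep(0.01, 3), lfc = rep(1, 3))
  ann <- data.frame(metabolite_id = c("A1", "A2", "A3"), family = "f",
                    stringsAsFactors = FALSE)
  serum <- data.frame(metabolite_id = c("B1", "B2"), logFC = 0, statistic = 0,
                      p = 0.5, fdr = 0.5, study = "S", stringsAsFactors = FALSE)
  expect_error(stratify_pathways(retina, ann, serum), "no metabolites overlap")
})
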
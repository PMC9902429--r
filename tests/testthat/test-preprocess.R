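test_that("log transform is the natural log and leaves the mask alone", {
  v <- matrix(c(exp(1), 4, NA, 9), 2, 2,
              dimnames = list(c("M1", "M2"), c("s1", "s2")))
  m <- abundance_matrix(v, scale = "raw")
  lg <- log_transform(m)
  expect_equal(values(lg)["M1", "s1"], 1.0)
  expect_identical(missing_mask(lg), missing_mask(m))
  expect_equal(abundance_scale(lg), "log")
  expect_error(log_transform(lg), "raw")
})

test_that("log transform symmetrizes a skewed peak-area distribution", {
  set.seed(5)
  x <- exp(rnorm(500, 2, 1))
  skew <- function(z) mean((z - mean(z))^3) / sd(z)^3
  expect_gt(abs(skew(x)), abs(skew(log(x))))
})

test_that("median normalization zeroes each group median and is shift invariant", {
  v <- matrix(c(1, 2, 3, 5, 7, 9), 1, 6,
              dimnames = list("M1", sprintf("s%d", 1:6)))
  sm <- tiny_samples(sprintf("s%d", 1:6),
                     regions = rep(c("macula", "periphery"), each = 3))
  sm$batch <- factor("B1")
  m <- abundance_matrix(v, scale = "raw")
  m$scale <- "log"   # treat the values as already-logged for exactness
  out <- median_normalize(m, sm)
  expect_equal(values(out)[1, 1:3], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(values(out)[1, 4:6], c(s4 = -2, s5 = 0, s6 = 2))
  grp <- rep(1:2, each = 3)
  for (g in 1:2)
    expect_lt(abs(median(values(out)[1, grp == g])), 1e-12)

  # adding a constant to one group's cells leaves that group's output unchanged
  v2 <- v; v2[1, 1:3] <- v2[1, 1:3] + 17
  m2 <- abundance_matrix(v2, scale = "raw"); m2$scale <- "log"
  out2 <- median_normalize(m2, sm)
  expect_equal(values(out2), values(out))
})

test_that("median normalization refuses groups with no observed values", {
  v <- matrix(c(NA, NA, NA, 1, 2, 3), 1, 6,
              dimnames = list("M1", sprintf("s%d", 1:6)))
  sm <- tiny_samples(sprintf("s%d", 1:6),
                     regions = rep(c("macula", "periphery"), each = 3))
  sm$batch <- factor("B1")
  m <- abundance_matrix(v, scale = "raw"); m$scale <- "log"
  expect_error(median_normalize(m, sm), "no observed values")
})

test_that("the missingness filter is inclusive at the cutoff and drops flat rows", {
  n <- 10
  v <- rbind(M1 = c(rep(NA, 9), 1),        # 0.90 missing
             M2 = c(rep(NA, 8), 1, 2),     # 0.80 missing
             M3 = c(rep(NA, 7), 1, 2, 3),  # 0.70 missing (one short of cutoff)
             M4 = rep(2, 10),              # constant
             M5 = rnorm(10))
  colnames(v) <- sprintf("s%02d", 1:n)
  out <- filter_metabolites(abundance_matrix(exp(v), scale = "raw"), 0.80)
  expect_setequal(out$dropped$metabolite_id, c("M1", "M2", "M4"))
  expect_equal(out$dropped$reason[out$dropped$metabolite_id == "M2"],
               "high_missingness")
  expect_equal(out$dropped$reason[out$dropped$metabolite_id == "M4"],
               "zero_variance")
  expect_setequal(rownames(values(out$matrix)), c("M3", "M5"))
  expect_error(filter_metabolites(abundance_matrix(
    matrix(2, 1, 3, dimnames = list("M1", c("a", "b", "c"))), scale = "raw")),
    "all metabolites dropped")
})

test_that("quantile normalization matches the hand-computed rank means", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  rownames(v) <- sprintf("M%d", 1:3)
  out <- quantile_normalize(abundance_matrix(v, scale = "imputed"))
  expect_equal(values(out)[, "s1"], c(M1 = 1.5, M2 = 3, M3 = 4.5))
  expect_equal(values(out)[, "s2"], c(M1 = 1.5, M2 = 3, M3 = 4.5))

  # identical columns are a fixed point
  v2 <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9))
  rownames(v2) <- sprintf("M%d", 1:3)
  out2 <- quantile_normalize(abundance_matrix(v2, scale = "imputed"))
  expect_equal(values(out2), v2)

  # all samples share one sorted vector afterwards, hence equal means
  v3 <- tiny_matrix(30, 8, seed = 6)
  out3 <- quantile_normalize(abundance_matrix(v3, scale = "imputed"))
  sorted <- apply(values(out3), 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_lt(diff(range(colMeans(values(out3)))), 1e-12)

  v3[1, 1] <- NA
  expect_error(quantile_normalize(abundance_matrix(v3, scale = "normalized")),
               "complete")
})

test_that("median then quantile normalization is idempotent once applied", {
  v <- tiny_matrix(24, 6, seed = 7)
  sm <- tiny_samples(colnames(v))
  g <- function(m) {
    m$scale <- "normalized"
    quantile_normalize(median_normalize(m, sm))
  }
  m0 <- abundance_matrix(v, scale = "imputed")
  once <- g(m0)
  twice <- g(once)
  expect_equal(values(twice), values(once), tolerance = 1e-12)
})

test_that("PCA QC flags a planted region mislabel via control metabolites", {
  st <- generate_study(generator_config(seed = 14))
  z <- quantile_normalize(set_scale(log_transform(st$abundance), "imputed"))
  ctrl <- st$truth$control_ids
  v <- values(z)
  # swap one macula sample's control levels down to periphery levels
  mac <- which(st$samples$region == "macula")[1]
  per <- which(st$samples$region == "periphery")[1]
  v[ctrl, mac] <- v[ctrl, per]
  z$values <- v
  qc <- pca_qc(z, st$samples, control_metabolite_ids = ctrl)
  mism <- qc$flagged[qc$flagged$reason == "control_metabolite_mismatch", ]
  expect_equal(nrow(mism), 1L)
  expect_equal(mism$sample_id, st$samples$sample_id[mac])

  # clean data: no control flags
  z2 <- quantile_normalize(set_scale(log_transform(st$abundance), "imputed"))
  qc2 <- pca_qc(z2, st$samples, control_metabolite_ids = ctrl)
  expect_equal(nrow(qc2$flagged[qc2$flagged$reason == "control_metabolite_mismatch", ]), 0L)

  expect_warning(pca_qc(z2, st$samples, control_metabolite_ids = "NOPE"),
                 "skipped")
})
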
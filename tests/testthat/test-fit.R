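test_that("standardization centres, scales, and is idempotent", {
  v <- matrix(c(1, 2, 3, 4, 6, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("M1", "M2"), c("a", "b", "c")))
  z <- standardize(abundance_matrix(v, scale = "imputed"))
  expect_equal(rowMeans(values(z)), c(M1 = 0, M2 = 0))
  expect_equal(apply(values(z), 1, sd), c(M1 = 1, M2 = 1))
  expect_equal(values(standardize(z)), values(z), tolerance = 1e-12)
  v[1, ] <- 5
  expect_error(standardize(abundance_matrix(v, scale = "imputed")), "zero-SD")
})

test_that("standardized logFC is the raw logFC divided by the metabolite SD", {
  st <- generate_study(generator_config(seed = 41, n_metabolites = 15))
  lg <- median_normalize(log_transform(st$abundance), st$samples)
  lg <- set_scale(lg, "imputed")
  raw_fit <- fit_abundance_model(lg, st$samples, rho = 0, moderate = FALSE)
  z_fit <- fit_abundance_model(standardize(lg), st$samples, rho = 0, moderate = FALSE)
  raw_res <- test_contrasts(raw_fit)
  z_res <- test_contrasts(z_fit)
  sds <- apply(values(lg), 1, sd)
  mvp_raw <- raw_res[raw_res$contrast == "macula_vs_periphery", ]
  mvp_z <- z_res[z_res$contrast == "macula_vs_periphery", ]
  expect_equal(mvp_z$logFC, mvp_raw$logFC / sds[mvp_z$metabolite_id],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("consensus correlation hits the clip under exact duplication and
           stays near zero for independent noise", {
  set.seed(42)
  n_m <- 50
  half <- matrix(rnorm(n_m * 6), n_m, 6)
  v <- cbind(half, half)                        # each sample duplicated
  ids <- sprintf("s%02d", 1:12)
  dimnames(v) <- list(sprintf("M%02d", 1:n_m), ids)
  sm <- data.frame(sample_id = ids, block = rep(sprintf("B%d", 1:6), 2))
  z <- abundance_matrix(v, scale = "imputed")
  est <- estimate_consensus_correlation(z, sm,
                                        design = matrix(1, 12, 1), block = "block")
  expect_gt(est$consensus, 0.95)

  v2 <- matrix(rnorm(200 * 12), 200, 12, dimnames = list(sprintf("M%03d", 1:200), ids))
  est2 <- estimate_consensus_correlation(abundance_matrix(v2, scale = "imputed"),
                                         sm, design = matrix(1, 12, 1), block = "block")
  expect_lt(abs(est2$consensus), 0.1)
})

test_that("with rho 0 and no moderation the pipeline reproduces OLS exactly", {
  st <- standardized_study(seed = 43, n_metabolites = 20)
  fit <- fit_abundance_model(st$z, st$samples, rho = 0, moderate = FALSE, block = NULL)
  res <- test_contrasts(fit)
  t_oracle <- ols_mvp_t(st$z, st$samples)
  mvp <- res[res$contrast == "macula_vs_periphery", ]
  expect_lt(max(abs(mvp$t - t_oracle[mvp$metabolite_id])), 1e-8)
})

test_that("a metabolite built as the macula indicator returns its amplitude", {
  st <- generate_study(generator_config(seed = 44, n_metabolites = 10,
                                        prop_region_affected = 0,
                                        control_metabolites = 0))
  v <- log(values(st$abundance))
  amp <- 2.5
  v["M001", ] <- 1 + amp * as.numeric(st$samples$region == "macula")
  m <- abundance_matrix(v, scale = "imputed")
  fit <- fit_abundance_model(m, st$samples, rho = 0, moderate = FALSE)
  res <- test_contrasts(fit)
  mvp <- res[res$contrast == "macula_vs_periphery" & res$metabolite_id == "M001", ]
  expect_equal(mvp$logFC, amp, tolerance = 1e-8)
  expect_gt(mvp$logFC, 0)      # sign contract for a macula-enriched metabolite
  expect_lt(fit$sigma2[["M001"]], 1e-16)
})

test_that("sample order does not affect the fit", {
  st <- standardized_study(seed = 45, n_metabolites = 12)
  perm <- sample(ncol(values(st$z)))
  z2 <- st$z; z2$values <- z2$values[, perm]
  fit1 <- fit_abundance_model(st$z, st$samples)
  fit2 <- fit_abundance_model(z2, st$samples)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-10)
})

test_that("variance moderation handles degenerate and limiting cases", {
  out <- moderate_variances(rep(0.7, 10), d = 20)
  expect_equal(out$d0, Inf)
  expect_equal(out$sigma2_post, rep(out$s0_sq, 10))

  s2 <- c(0.5, 1, 2, 4)
  none <- list(d0 = 0, s0_sq = NA, sigma2_post = s2)
  expect_equal((0 * 1 + 20 * s2) / (0 + 20), none$sigma2_post)
  expect_error(moderate_variances(c(1, 2), 5), "at least 3")
  expect_error(moderate_variances(c(1, -1, 2), 5), "positive")
})

test_that("the moderation prior is recovered from simulated variances", {
  set.seed(46)
  d0 <- 8; s0 <- 0.6; d <- 26; n_m <- 2000
  sigma2 <- d0 * s0 / rchisq(n_m, d0)          # scaled inverse chi-square
  s2 <- sigma2 * rchisq(n_m, d) / d
  est <- moderate_variances(s2, d)
  expect_lt(abs(est$d0 - d0) / d0, 0.25)
  expect_lt(abs(est$s0_sq - s0) / s0, 0.15)
})

test_that("moderation agrees with the established empirical-Bayes reference", {
  st <- standardized_study(seed = 47, n_metabolites = 200)
  fit <- fit_abundance_model(st$z, st$samples, rho = 0, block = NULL)
  sm <- st$samples; sm$age <- sm$age - mean(sm$age)
  X <- model.matrix(~ region + age + sex + batch, sm)
  lf <- limma::eBayes(limma::lmFit(values(st$z), X))
  expect_lt(abs(fit$prior$d0 - lf$df.prior) / lf$df.prior, 0.25)
  expect_lt(abs(fit$prior$s0_sq - lf$s2.prior) / lf$s2.prior, 0.1)
  expect_lt(max(abs(fit$sigma2_post - lf$s2.post) / lf$s2.post), 0.1)
  # moderated t for macula - periphery = -regionperiphery coefficient
  res <- test_contrasts(fit)
  mvp <- res[res$contrast == "macula_vs_periphery", ]
  t_limma <- -lf$t[, "regionperiphery"]
  expect_gt(cor(mvp$t, t_limma[mvp$metabolite_id]), 0.999)
})

test_that("BH adjustment and flags follow the textbook formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  st <- standardized_study(seed = 48, n_metabolites = 50)
  res <- test_contrasts(fit_abundance_model(st$z, st$samples))
  expect_true(all(res$fdr >= res$p))
  expect_identical(res$significant, res$fdr < 0.05)
  for (ct in unique(res$contrast)) {
    sub <- res[res$contrast == ct, ]
    ord <- order(sub$p)
    expect_true(all(diff(sub$fdr[ord]) >= -1e-12))   # BH is monotone
  }
})

test_that("covariate and interaction coefficients are reported per metabolite", {
  st <- standardized_study(seed = 49, n_metabolites = 20)
  fit <- fit_abundance_model(st$z, st$samples)
  cov <- covariate_effects(fit)
  expect_setequal(unique(cov$term), c("age", "sexM", "batchB2", "batchB3"))
  expect_equal(sum(cov$term == "age"), 20L)

  fit_int <- fit_abundance_model(st$z, st$samples, interactions = "age:region")
  cov_int <- covariate_effects(fit_int)
  expect_true(any(grepl("region.*age|age.*region", cov_int$term)))
})

test_that("a rank-deficient design is rejected with the aliased column named", {
  st <- standardized_study(seed = 50, n_metabolites = 5)
  sm <- st$samples
  sm$dup <- as.numeric(sm$region == "temporal")
  expect_error(fit_abundance_model(st$z, sm, covariates = c("age", "sex", "batch", "dup")),
               "aliased|rank")
})

test_that("model methods print and summarize without error", {
  st <- standardized_study(seed = 51, n_metabolites = 30)
  fit <- fit_abundance_model(st$z, st$samples)
  expect_output(print(fit), "abundance_fit")
  s <- summary(fit)
  expect_output(print(s), "significant metabolites")
  expect_equal(dim(coef(fit)), c(30L, 7L))
  expect_equal(nrow(residuals(fit)), 30L)
})
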
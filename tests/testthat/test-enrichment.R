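test_that("rotation p-values centre near 0.5 for null sets", {
  st <- standardized_study(seed = 61, prop_region_affected = 0,
                           control_metabolites = 0)
  fit <- fit_abundance_model(st$z, st$samples)
  set.seed(1)
  sets <- lapply(1:50, function(i) sample(rownames(values(st$z)), 10))
  names(sets) <- paste0("set", 1:50)
  res <- rotation_set_test(fit, sets, n_rotations = 499, seed = 2)
  expect_false(any(res$skipped))
  expect_lt(abs(mean(res$p_up) - 0.5), 0.12)
  expect_true(all(res$p_up > 0 & res$p_up <= 1))
  expect_true(all(res$p_mixed > 0 & res$p_mixed <= 1))
})

test_that("a planted family shift is detected with a tiny p-value", {
  cfg <- generator_config(seed = 62, prop_region_affected = 0, control_metabolites = 0)
  st <- generate_study(cfg)
  members <- names(st$truth$family)[st$truth$family == "family_05"]
  v <- values(st$abundance)
  mac <- st$samples$region == "macula"
  v[members, mac] <- v[members, mac] * exp(1)    # +1 log unit in the macula
  st$abundance$values <- v
  z <- standardize(median_normalize(log_transform(st$abundance), st$samples))
  fit <- fit_abundance_model(z, st$samples)
  res <- rotation_set_test(fit, list(planted = members), n_rotations = 9999, seed = 3)
  expect_lt(res$p_up, 0.005)
})

test_that("rotation p-values agree with a sample-permutation oracle", {
  # simple design: region only, independent samples, no moderation
  set.seed(63)
  n <- 18
  regions <- rep(c("macula", "temporal", "periphery"), each = 6)
  ids <- sprintf("s%02d", 1:n)
  sm <- data.frame(sample_id = ids, subject_id = ids, eye = "left",
                   region = regions, sex = "F", age = 2, batch = "B1",
                   stringsAsFactors = FALSE)
  sm <- sample_table(sm)
  v <- matrix(rnorm(12 * n), 12, n, dimnames = list(sprintf("M%02d", 1:12), ids))
  z <- standardize(abundance_matrix(v, scale = "imputed"))
  members <- sprintf("M%02d", 1:5)
  fit <- fit_abundance_model(z, sm, covariates = character(0), block = NULL,
                             rho = 0, moderate = FALSE)
  p_rot <- rotation_set_test(fit, list(s = members), n_rotations = 1999,
                             seed = 4)$p_up
  # permutation oracle: permute region labels, refit, recompute the set mean t
  obs <- mean(test_contrasts(fit)$t[test_contrasts(fit)$contrast ==
                                      "macula_vs_periphery"][1:5])
  null_means <- replicate(600, {
    sm2 <- sm; sm2$region <- sm$region[sample(n)]
    f2 <- fit_abundance_model(z, sm2, covariates = character(0), block = NULL,
                              rho = 0, moderate = FALSE)
    r2 <- test_contrasts(f2)
    mean(r2$t[r2$contrast == "macula_vs_periphery"][1:5])
  })
  p_perm <- (1 + sum(null_means >= obs)) / (600 + 1)
  expect_lt(abs(p_rot - p_perm), 0.1)
})

test_that("direction calls follow the significance rules", {
  res <- data.frame(pathway = c("a", "b", "c", "d"),
                    n_metabolites = 5,
                    mean_t = c(2, -2, 0, 0.1),
                    p_up = c(1e-5, 0.9, 0.5, 0.4),
                    p_down = c(0.9, 1e-5, 0.6, 0.5),
                    p_mixed = c(0.2, 0.2, 1e-5, 0.6),
                    skipped = FALSE, stringsAsFactors = FALSE)
  out <- classify_direction(res, fdr_cutoff = 0.05)
  expect_equal(out$call, c("enriched", "depleted", "mixed", "none"))
  # totality: every tested row receives exactly one call
  expect_false(anyNA(out$call))
})

test_that("undersized sets are skipped, not tested", {
  st <- standardized_study(seed = 64, n_metabolites = 30)
  fit <- fit_abundance_model(st$z, st$samples)
  res <- rotation_set_test(fit, list(tiny = c("M001", "M002")),
                           n_rotations = 99, min_subset_size = 3, seed = 1)
  expect_true(res$skipped)
  expect_true(is.na(res$p_up))
  out <- classify_direction(res)
  expect_true(is.na(out$call))
})

test_that("pathway PC scores handle singleton, duplicated and flipped members", {
  v <- tiny_matrix(6, 12, seed = 65)
  v["M02", ] <- 2 * v["M01", ] - 3          # perfectly correlated pair
  z <- standardize(abundance_matrix(v, scale = "imputed"))
  ann <- data.frame(metabolite_id = rownames(v),
                    family = c("pair", "pair", "solo", "rest", "rest", "rest"),
                    stringsAsFactors = FALSE)
  ps <- pathway_pc_scores(z, ann)
  expect_equal(ps$explained[["pair"]], 1.0, tolerance = 1e-12)
  expect_equal(unname(ps$scores["solo", ]), unname(values(z)["M03", ]),
               tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(ps$scores))), 1e-10)

  # flipping every member's sign flips the scores, not two-sided inference
  z2 <- z; z2$values <- -z2$values
  ps2 <- pathway_pc_scores(z2, ann)
  expect_equal(abs(ps2$scores["rest", ]), abs(ps$scores["rest", ]),
               tolerance = 1e-8)
})

test_that("pathway PC differential testing finds a planted family shift", {
  cfg <- generator_config(seed = 66, prop_region_affected = 0, control_metabolites = 0)
  st <- generate_study(cfg)
  members <- names(st$truth$family)[st$truth$family == "family_03"]
  v <- values(st$abundance)
  mac <- st$samples$region == "macula"
  v[members, mac] <- v[members, mac] * exp(1.5)
  st$abundance$values <- v
  z <- standardize(median_normalize(log_transform(st$abundance), st$samples))
  ps <- pathway_pc_scores(z, st$annotation)
  res <- pathway_pc_differential(ps, st$samples, rho = 0.5)
  hit <- res[res$metabolite_id == "family_03" &
               res$contrast == "macula_vs_periphery", ]
  expect_true(hit$significant)
  # null families stay mostly quiet
  null_mvp <- res[res$metabolite_id != "family_03" &
                    res$contrast == "macula_vs_periphery", ]
  expect_lt(mean(null_mvp$significant), 0.2)
})
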
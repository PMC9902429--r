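# Small fixtures shared across test files. Everything is built in code.

# a tiny named matrix with optional NA cells
tiny_matrix <- function(nr = 4, nc = 6, seed = 1, miss = 0, mu = 10, sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nr * nc, mu, sd), nr, nc,
              dimnames = list(sprintf("M%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  if (miss > 0) v[sample(length(v), round(miss * length(v)))] <- NA
  v
}

# retag the pipeline scale of a matrix (tests sometimes skip stages)
set_scale <- function(m, s) { m$scale <- s; m }

# a minimal valid sample table for n samples split over three regions
tiny_samples <- function(ids, regions = NULL) {
  n <- length(ids)
  if (is.null(regions)) regions <- rep(c("macula", "temporal", "periphery"),
                                       length.out = n)
  sample_table(data.frame(
    sample_id = ids,
    subject_id = rep(sprintf("S%d", 1:2), length.out = n),
    eye = rep(c("left", "right"), length.out = n),
    region = regions,
    sex = rep(c("F", "M"), length.out = n),
    age = seq(1.5, 3, length.out = n),
    batch = rep(c("B1", "B2"), length.out = n),
    stringsAsFactors = FALSE))
}

# a complete default-design study on the log scale, standardized, plus truth
standardized_study <- function(seed, ...) {
  cfg <- generator_config(seed = seed, ...)
  st <- generate_study(cfg)
  st$z <- standardize(median_normalize(log_transform(st$abundance), st$samples))
  st
}

# brute-force auxiliary search: enumerate all candidates, rank as documented
brute_force_aux <- function(v, focal_id, min_overlap = 3) {
  focal <- v[focal_id, ]
  cand <- list()
  for (id in setdiff(rownames(v), focal_id)) {
    both <- !is.na(focal) & !is.na(v[id, ])
    if (sum(both) < min_overlap) next
    r <- suppressWarnings(cor(focal[both], v[id, both]))
    if (is.na(r)) next
    cand[[length(cand) + 1L]] <- data.frame(id = id, r = r, n = sum(both),
                                            stringsAsFactors = FALSE)
  }
  if (length(cand) < 2) return(NULL)
  d <- do.call(rbind, cand)
  d <- d[order(-d$r, -d$n, d$id), ]
  list(aux1_id = d$id[1], aux2_id = d$id[2], r1 = d$r[1], r2 = d$r[2])
}

# per-metabolite OLS t for the macula - periphery contrast (textbook oracle)
ols_mvp_t <- function(z, samples) {
  sm <- samples
  sm$age <- sm$age - mean(sm$age)
  sapply(rownames(z$values), function(id) {
    d <- cbind(sm, y = z$values[id, ])
    co <- summary(lm(y ~ region + age + sex + batch, data = d))$coefficients
    -co["regionperiphery", "t value"]
  })
}
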
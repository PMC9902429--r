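#' Synthetic study generator configuration
#'
#' Defaults emulate a paired-eye, three-region primate retina metabolomics
#' design: 6 subjects (3 female / 3 male, ages around 2.1 y), both eyes for
#' all but one subject, three retinal regions per eye (33 samples), three
#' preparation batches, 371 metabolites in 34 biochemical families, overall
#' missingness around 26% rising from macula to periphery, and a small set of
#' macula-marker control metabolites.
#'
#' @param n_subjects number of subjects.
#' @param paired_eyes if `TRUE`, subjects contribute both eyes except for
#'   `n_single_eye_subjects` of them.
#' @param n_single_eye_subjects subjects contributing only one eye.
#' @param n_metabolites,n_families,n_batches dataset dimensions.
#' @param prop_region_affected proportion of families given a true region
#'   effect.
#' @param region_effect_sd SD (natural-log units) of family-level region
#'   offsets.
#' @param subject_corr_rho within-subject correlation of log abundances
#'   induced by the subject random effect (fraction of unit residual
#'   variance assigned to the subject effect).
#' @param family_corr residual correlation between metabolites of the same
#'   biochemical family (a family-shared residual component mimicking
#'   co-regulation; auxiliary-metabolite search depends on it). The
#'   within-subject correlation is unaffected by this parameter.
#' @param batch_sd,sex_effect_sd,age_effect_sd SDs (log units) of batch
#'   offsets and of per-metabolite sex/age coefficients.
#' @param target_missing_overall target overall missing fraction.
#' @param mnar_fraction proportion of metabolites whose missingness is
#'   left-censored (MNAR).
#' @param region_missing_targets per-region missing-fraction targets, ordered
#'   macula, temporal, periphery.
#' @param mnar_censor_prop fraction of an MNAR metabolite's values below its
#'   censoring threshold.
#' @param control_metabolites number of macula-marker control metabolites.
#' @param control_effect fixed macula-only log enrichment of the controls.
#'   The default of 6 natural-log units (~400-fold) mirrors the drastic
#'   macular enrichment of the xanthophyll pigments used as dissection
#'   controls in primate retina work.
#' @param seed integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 6L,
                             paired_eyes = TRUE,
                             n_single_eye_subjects = 1L,
                             n_metabolites = 371L,
                             n_families = 34L,
                             n_batches = 3L,
                             prop_region_affected = 0.5,
                             region_effect_sd = 1.0,
                             subject_corr_rho = 0.5,
                             family_corr = 0.5,
                             batch_sd = 0.3,
                             sex_effect_sd = 0.2,
                             age_effect_sd = 0.2,
                             target_missing_overall = 0.26,
                             mnar_fraction = 0.2,
                             region_missing_targets = c(macula = 0.24, temporal = 0.257, periphery = 0.284),
                             mnar_censor_prop = 0.26,
                             control_metabolites = 2L,
                             control_effect = 6.0,
                             seed = 1L) {
  if (n_subjects < 1) stop("impossible design: need at least one subject")
  if (n_single_eye_subjects > n_subjects)
    stop("n_single_eye_subjects cannot exceed n_subjects")
  props <- c(prop_region_affected, subject_corr_rho, family_corr, target_missing_overall,
             mnar_fraction, mnar_censor_prop, region_missing_targets)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (is.unsorted(region_missing_targets))
    warning("region missingness targets are not ordered macula <= temporal <= periphery")
  structure(as.list(environment()), class = "generator_config")
}

# internal: sample layout for the paired-eye three-region design
build_sample_table <- function(cfg) {
  subj <- sprintf("S%d", seq_len(cfg$n_subjects))
  sex <- rep(c("F", "M"), length.out = cfg$n_subjects)
  age <- pmax(0.5, stats::rnorm(cfg$n_subjects, 2.1, 0.94))
  eyes_per <- if (cfg$paired_eyes) rep(2L, cfg$n_subjects) else rep(1L, cfg$n_subjects)
  if (cfg$paired_eyes && cfg$n_single_eye_subjects > 0)
    eyes_per[seq_len(cfg$n_single_eye_subjects)] <- 1L
  batch_of_subject <- rep(seq_len(cfg$n_batches), length.out = cfg$n_subjects)
  rows <- list()
  regions <- c("macula", "temporal", "periphery")
  for (i in seq_len(cfg$n_subjects)) {
    eyes <- if (eyes_per[i] == 2) c("left", "right") else "right"
    for (e in eyes) for (r in regions) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%s", subj[i], substr(e, 1, 1), r),
        subject_id = subj[i], eye = e, region = r, sex = sex[i],
        age = age[i], batch = sprintf("B%d", batch_of_subject[i]),
        stringsAsFactors = FALSE)
    }
  }
  sample_table(do.call(rbind, rows))
}

#' Generate a synthetic region-resolved metabolomics study
#'
#' Draws a complete (no missing cells) raw abundance matrix on the model
#' `log A_ms = mu_m + region_m[r(s)] + u_{m,subject(s)} + b_{m,batch(s)} +
#' beta_sex,m 1(F) + beta_age,m (age - mean age) + eps_ms`. Region offsets are
#' drawn per biochemical family and jittered per metabolite, so enrichment
#' signal exists at the family level; the subject random effect carries
#' `subject_corr_rho` of the unit residual variance, inducing that
#' within-subject correlation on the log scale. Control metabolites receive a
#' fixed macula-only enrichment.
#'
#' @param config a [generator_config()].
#' @return A list with elements `abundance` (raw `abundance_matrix`),
#'   `samples` (sample table), `annotation` (pathway annotation data frame)
#'   and `truth` (ground-truth list: `region_effects` metabolite x 3 matrix,
#'   `non_null`, `family`, `mechanism`, `censor_threshold`, `subject_corr_rho`,
#'   `batch_effects`, `sex_effects`, `age_effects`, `affected_families`,
#'   `control_ids`).
#' @export
generate_study <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  samples <- build_sample_table(cfg)
  n <- nrow(samples)
  m <- cfg$n_metabolites
  met <- sprintf("M%03d", seq_len(m))
  fam_names <- sprintf("family_%02d", seq_len(cfg$n_families))
  family <- factor(fam_names[rep(seq_len(cfg$n_families), length.out = m)],
                   levels = fam_names)
  annotation <- data.frame(metabolite_id = met, family = as.character(family),
                           super_family = ifelse(as.integer(family) <= cfg$n_families / 2,
                                                 "lipid", "non_lipid"),
                           stringsAsFactors = FALSE)

  # family-level region offsets, jittered per metabolite
  affected_fam <- fam_names[stats::runif(cfg$n_families) < cfg$prop_region_affected]
  fam_eff <- matrix(0, cfg$n_families, 3,
                    dimnames = list(fam_names, c("macula", "temporal", "periphery")))
  idx <- fam_names %in% affected_fam
  fam_eff[idx, ] <- stats::rnorm(sum(idx) * 3, 0, cfg$region_effect_sd)
  fam_eff <- fam_eff - rowMeans(fam_eff)   # offsets relative to the regional mean
  region_eff <- fam_eff[as.integer(family), , drop = FALSE]
  jitter_sd <- 0.3 * cfg$region_effect_sd
  region_eff[as.character(family) %in% affected_fam, ] <-
    region_eff[as.character(family) %in% affected_fam, ] +
    stats::rnorm(sum(as.character(family) %in% affected_fam) * 3, 0, jitter_sd)
  rownames(region_eff) <- met

  control_ids <- character(0)
  if (cfg$control_metabolites > 0) {
    control_ids <- met[seq_len(cfg$control_metabolites)]
    region_eff[control_ids, ] <- 0
    region_eff[control_ids, "macula"] <- cfg$control_effect
  }
  non_null <- apply(region_eff, 1, function(z) max(z) - min(z)) > 0

  mu <- stats::rnorm(m, 10, 1)                 # baseline log peak area
  rho <- cfg$subject_corr_rho
  fc <- cfg$family_corr
  subj_ids <- unique(samples$subject_id)
  subj_of <- match(samples$subject_id, subj_ids)
  # residual = sqrt(fc) * (family-shared component) + sqrt(1-fc) * (own
  # component); both components carry the subject/noise split, so the
  # within-subject correlation is rho regardless of fc
  cs_resid <- function(nrows) {
    u <- matrix(stats::rnorm(nrows * length(subj_ids), 0, sqrt(rho)),
                nrows, length(subj_ids))
    u[, subj_of, drop = FALSE] +
      matrix(stats::rnorm(nrows * n, 0, sqrt(1 - rho)), nrows, n)
  }
  resid_fam <- cs_resid(cfg$n_families)
  resid_own <- cs_resid(m)
  resid <- sqrt(fc) * resid_fam[as.integer(family), , drop = FALSE] +
    sqrt(1 - fc) * resid_own
  batches <- levels(samples$batch)
  b <- matrix(stats::rnorm(m * length(batches), 0, cfg$batch_sd),
              m, length(batches), dimnames = list(met, batches))
  beta_sex <- stats::rnorm(m, 0, cfg$sex_effect_sd)
  beta_age <- stats::rnorm(m, 0, cfg$age_effect_sd)
  age_c <- samples$age - mean(samples$age)

  logA <- mu +
    region_eff[, as.integer(samples$region), drop = FALSE] +
    b[, as.integer(samples$batch), drop = FALSE] +
    outer(beta_sex, as.numeric(samples$sex == "F")) +
    outer(beta_age, age_c) +
    resid
  dimnames(logA) <- list(met, samples$sample_id)

  mech <- rep("MAR", m)
  n_mnar <- round(cfg$mnar_fraction * m)
  if (n_mnar > 0) {
    # censor well-behaved non-control metabolites, spread across families
    cand <- setdiff(met, control_ids)
    mech[met %in% cand[unique(round(seq(1, length(cand), length.out = n_mnar)))]] <- "MNAR"
  }
  censor <- rep(NA_real_, m)
  censor[mech == "MNAR"] <- apply(logA[mech == "MNAR", , drop = FALSE], 1,
                                  stats::quantile, probs = cfg$mnar_censor_prop,
                                  names = FALSE)
  names(mech) <- names(censor) <- met

  truth <- list(region_effects = region_eff, non_null = non_null,
                family = stats::setNames(as.character(family), met),
                mechanism = mech, censor_threshold = censor,
                subject_corr_rho = rho, batch_effects = b,
                sex_effects = stats::setNames(beta_sex, met),
                age_effects = stats::setNames(beta_age, met),
                affected_families = affected_fam, control_ids = control_ids)
  list(abundance = abundance_matrix(exp(logA), scale = "raw"),
       samples = samples, annotation = annotation, truth = truth)
}

#' Delete cells according to the configured missingness mechanisms
#'
#' MNAR metabolites lose every cell whose log value lies below their
#' ground-truth censoring threshold (left-censoring). MAR metabolites lose
#' cells uniformly at random at per-region rates solved analytically so the
#' realized overall missingness approximates `target_missing_overall` with the
#' configured macula-to-periphery gradient.
#'
#' @param study a study list from [generate_study()].
#' @param config the [generator_config()] used to build the study.
#' @return The study list with `abundance` masked (still `scale = "raw"`).
#' @export
apply_missingness <- function(study, config = generator_config()) {
  cfg <- config
  if (anyNA(study$abundance$values)) stop("matrix already contains missing cells")
  set.seed(cfg$seed + 104729L)  # independent stream from the study draw
  v <- study$abundance$values
  logv <- log(v)
  mech <- study$truth$mechanism
  censor <- study$truth$censor_threshold
  mnar <- names(mech)[mech == "MNAR"]
  for (id in mnar) v[id, logv[id, ] < censor[id]] <- NA_real_

  # analytic MAR rates: region target = mnar_share * censor_prop + mar_share * rate
  mnar_share <- length(mnar) / nrow(v)
  regions <- levels(study$samples$region)
  targets <- cfg$region_missing_targets
  # rescale the gradient so its mean matches the overall target
  if (cfg$target_missing_overall > 0 && mean(targets) > 0) {
    targets <- targets * cfg$target_missing_overall / mean(targets)
  } else {
    targets <- rep(0, length(targets))
  }
  mar_rows <- mech != "MNAR"
  for (k in seq_along(regions)) {
    rate <- (targets[k] - mnar_share * cfg$mnar_censor_prop) / (1 - mnar_share)
    rate <- min(max(rate, 0), 1)
    cols <- which(study$samples$region == regions[k])
    if (rate > 0 && any(mar_rows)) {
      hit <- matrix(stats::runif(sum(mar_rows) * length(cols)) < rate,
                    nrow = sum(mar_rows))
      block <- v[mar_rows, cols, drop = FALSE]
      block[hit] <- NA_real_
      v[mar_rows, cols] <- block
    }
  }
  study$abundance <- set_values(study$abundance, v)
  study
}

#' Generate a synthetic case/control serum metabolomics study
#'
#' Two-group log-normal abundances with family-level shared case-vs-control
#' shifts for the affected families, reusable by the differential-abundance
#' fit to produce serum summary statistics for the disease-overlap stage.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_metabolites number of metabolites.
#' @param annotation pathway annotation data frame (`metabolite_id`, `family`);
#'   defaults to cycling 34 families as in [generate_study()].
#' @param affected_families character vector of family names given a shift.
#' @param effect_sd SD (log units) of the family-level case shift; 0 makes
#'   every family null.
#' @param seed integer seed.
#' @return List with `abundance` (raw matrix), `samples` (data frame with
#'   `sample_id`, `group` in {case, control}) and `truth` (family shifts and
#'   per-metabolite true effects).
#' @export
generate_serum_study <- function(n_cases, n_controls, n_metabolites = 371L,
                                 annotation = NULL,
                                 affected_families = character(0),
                                 effect_sd = 0.5, seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("group sizes must be positive")
  set.seed(seed)
  met <- sprintf("M%03d", seq_len(n_metabolites))
  if (is.null(annotation)) {
    fam_names <- sprintf("family_%02d", seq_len(34L))
    annotation <- data.frame(metabolite_id = met,
                             family = fam_names[rep(seq_len(34L), length.out = n_metabolites)],
                             stringsAsFactors = FALSE)
  }
  annotation <- annotation[match(met, annotation$metabolite_id), , drop = FALSE]
  fam <- annotation$family
  fams <- unique(fam)
  shift <- stats::setNames(rep(0, length(fams)), fams)
  aff <- intersect(affected_families, fams)
  if (effect_sd > 0 && length(aff))
    shift[aff] <- stats::rnorm(length(aff), 0, effect_sd)
  eff <- shift[fam] + ifelse(fam %in% aff & effect_sd > 0,
                             stats::rnorm(n_metabolites, 0, 0.3 * effect_sd), 0)
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  mu <- stats::rnorm(n_metabolites, 10, 1)
  logA <- mu + outer(eff, as.numeric(group == "case")) +
    matrix(stats::rnorm(n_metabolites * n), n_metabolites, n)
  sid <- sprintf("P%03d", seq_len(n))
  dimnames(logA) <- list(met, sid)
  list(abundance = abundance_matrix(exp(logA), scale = "raw"),
       samples = data.frame(sample_id = sid, group = factor(group, c("control", "case")),
                            stringsAsFactors = FALSE),
       truth = list(family_shift = shift, metabolite_effect = stats::setNames(eff, met),
                    affected_families = aff),
       annotation = annotation)
}
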
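#' @title Synthetic staged-cohort generator
#' @description
#' Simulates cohorts shaped like a newly diagnosed myeloma case series:
#' demographics, a laboratory panel, an IMPeTUs PET/CT descriptor drawn
#' from the reference token vocabulary, the three stage labels derived
#' by the package's own rule engines (so labels are always internally
#' consistent with the generated labs and imaging), and right-censored
#' overall-survival times from a proportional-hazards model with
#' stage-dependent hazard ratios.  Every analysis step of the package
#' can therefore be exercised against known ground truth.
#' @name synthetic-cohort
NULL

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the 33-patient reference cohort
#' ([fixture_table2()]): token frequencies for the descriptor
#' distribution are the empirical Table frequencies of that cohort, lab
#' distributions are centred on typical newly diagnosed myeloma values
#' with roughly a third of patients renally impaired (creatinine >= 2
#' mg/dL), and the survival model's default hazard-ratio presets are the
#' effect sizes reported for such cohorts (DS Plus II ~4.8, DS Plus III
#' ~11.5 vs stage I; marrow Deauville >= 4 ~3.5; extramedullary disease
#' ~1.5).  The presets are demonstration effect sizes, not estimates.
#'
#' @param n_patients cohort size.
#' @param labs list of lab-distribution parameters: normal
#'   hemoglobin/calcium/albumin (`*_mean`, `*_sd`), log-normal
#'   beta-2-microglobulin (`beta2m_meanlog`, `beta2m_sdlog`), a
#'   two-component creatinine mixture (`creatinine_p_high` and
#'   normal low/high components), `p_ldh_elevated`, `p_high_risk_ca`,
#'   and M-component parameters by myeloma type.
#' @param descriptor list of token probabilities: `bm_score_probs`
#'   (Deauville 1-5), `p_bm_appendicular`, `p_focal`,
#'   `focal_grade_probs` (grades 1-4 given a focal token),
#'   `focal_score_probs`, per-site probabilities `p_skull`, `p_spine`,
#'   `p_extraspine`, `lytic_grade_probs`, `p_fracture`, `p_pm`, `p_em`,
#'   `em_site_probs` (nodal only / extranodal only / both),
#'   `em_score_probs`.
#' @param survival list: `baseline` (`"exponential"` or `"weibull"`),
#'   `median_stage_i` baseline median OS in months, `weibull_shape`,
#'   hazard ratios `hr_stage_ii`, `hr_stage_iii` (vs DS Plus stage I),
#'   `hr_bm_ge4`, `hr_emd`, and `censor_window_months` for uniform
#'   administrative censoring.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 33,
                          labs = list(),
                          descriptor = list(),
                          survival = list()) {
  cfg <- list(
    n_patients = n_patients,
    labs = modify_defaults(list(
      hemoglobin_mean = 9.5, hemoglobin_sd = 2.2,
      calcium_mean = 9.8, calcium_sd = 1.3,
      albumin_mean = 3.6, albumin_sd = 0.6,
      beta2m_meanlog = log(4.2), beta2m_sdlog = 0.7,
      creatinine_p_high = 1 / 3,
      creatinine_low_mean = 1.0, creatinine_low_sd = 0.3,
      creatinine_high_mean = 3.2, creatinine_high_sd = 1.0,
      p_ldh_elevated = 0.3, p_high_risk_ca = 0.25,
      type_probs = c("IgG" = 0.64, "IgA" = 0.06, "Light chain" = 0.24,
                     "Other" = 0.06),
      igg_meanlog = log(4.5), igg_sdlog = 0.5,
      iga_meanlog = log(3.0), iga_sdlog = 0.5,
      bence_jones_meanlog = log(4), bence_jones_sdlog = 0.8
    ), labs),
    descriptor = modify_defaults(list(
      bm_score_probs = c(0, 13, 10, 8, 2) / 33,
      p_bm_appendicular = 9 / 33,
      p_focal = 31 / 33,
      focal_grade_probs = c(1, 5, 5, 20) / 31,
      focal_score_probs = c(0, 1, 3, 16, 10) / 30,
      p_skull = 6 / 31, p_spine = 28 / 31, p_extraspine = 22 / 31,
      lytic_grade_probs = c(5, 8, 5, 13) / 31,
      p_fracture = 0.02, p_pm = 18 / 33, p_em = 22 / 33,
      em_site_probs = c(nodal = 4 / 22, extranodal = 14 / 22,
                        both = 4 / 22),
      em_score_probs = c(0, 2, 5, 7, 8) / 22
    ), descriptor),
    survival = modify_defaults(list(
      baseline = "exponential",
      median_stage_i = 72,
      weibull_shape = 1,
      hr_stage_ii = 4.818, hr_stage_iii = 11.539,
      hr_bm_ge4 = 3.487, hr_emd = 1.463,
      censor_window_months = 120
    ), survival)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients)) {
    stop("n_patients must be a nonnegative integer", call. = FALSE)
  }
  d <- cfg$descriptor
  probs <- c(d$p_bm_appendicular, d$p_focal, d$p_skull, d$p_spine,
             d$p_extraspine, d$p_fracture, d$p_pm, d$p_em,
             cfg$labs$creatinine_p_high, cfg$labs$p_ldh_elevated,
             cfg$labs$p_high_risk_ca)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("bm_score_probs", "focal_grade_probs", "focal_score_probs",
               "lytic_grade_probs", "em_score_probs", "em_site_probs")) {
    p <- d[[nm]]
    if (any(p < 0) || sum(p) <= 0) {
      stop(nm, " must be nonnegative with positive sum", call. = FALSE)
    }
  }
  s <- cfg$survival
  if (!s$baseline %in% c("exponential", "weibull")) {
    stop("baseline must be 'exponential' or 'weibull'", call. = FALSE)
  }
  pos <- c(s$median_stage_i, s$weibull_shape, s$hr_stage_ii,
           s$hr_stage_iii, s$hr_bm_ge4, s$hr_emd,
           s$censor_window_months)
  if (any(!is.finite(pos) | pos <= 0)) {
    stop("survival scale parameters and hazard ratios must be positive",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw a random IMPeTUs descriptor
#'
#' Samples a descriptor from the configured token distribution,
#' optionally rejection-sampling until the DS Plus engine assigns a
#' requested stage -- the engine itself is the arbiter, so
#' stage-conditional draws are correct by construction.
#'
#' @param config a [cohort_config()].
#' @param stage_target optional `"I"`, `"II"` or `"III"` (collapsed DS
#'   Plus stage).
#' @param max_attempts rejection-sampling budget before erroring.
#' @param staging a [staging_config()] used when `stage_target` is set.
#' @return An [impetus_descriptor()].
#' @export
generate_descriptor <- function(config = cohort_config(),
                                stage_target = NULL,
                                max_attempts = 1000L,
                                staging = staging_config()) {
  if (is.null(stage_target)) return(random_descriptor(config$descriptor))
  stopifnot(stage_target %in% STAGES)
  for (i in seq_len(max_attempts)) {
    d <- random_descriptor(config$descriptor)
    if (stage_dsplus(d, config = staging)$stage == stage_target) return(d)
  }
  stop("no descriptor reaching DS Plus stage ", stage_target, " in ",
       max_attempts, " attempts under this configuration", call. = FALSE)
}

random_descriptor <- function(dc) {
  bm <- sample(1:5, 1L, prob = dc$bm_score_probs)
  focal <- stats::runif(1) < dc$p_focal
  fg <- NA_integer_; fs <- character(); fsc <- NA_integer_
  lg <- NA_integer_
  if (focal) {
    fg <- sample(1:4, 1L, prob = dc$focal_grade_probs)
    if (fg > 1L) {
      fs <- c("skull", "spine", "extraspine")[
        stats::runif(3) < c(dc$p_skull, dc$p_spine, dc$p_extraspine)]
      if (!length(fs)) fs <- "spine"
      fsc <- sample(1:5, 1L, prob = dc$focal_score_probs)
    }
    lg <- sample(1:4, 1L, prob = dc$lytic_grade_probs)
    if (lg > fg) lg <- fg  # lytic lesions are a subset of focal lesions
  }
  em <- stats::runif(1) < dc$p_em
  em_sites <- empty_em_sites()
  if (em) {
    kind <- sample(names(dc$em_site_probs), 1L, prob = dc$em_site_probs)
    sites <- switch(kind, nodal = "nodal", extranodal = "extranodal",
                    both = c("nodal", "extranodal"))
    em_sites <- data.frame(
      site = sites,
      score = sample(1:5, length(sites), replace = TRUE,
                     prob = dc$em_score_probs),
      stringsAsFactors = FALSE)
  }
  impetus_descriptor(
    bm_score = bm,
    bm_appendicular = stats::runif(1) < dc$p_bm_appendicular,
    focal_grade = fg, focal_sites = fs, focal_score = fsc,
    lytic_grade = lg,
    fracture = stats::runif(1) < dc$p_fracture,
    paramedullary = stats::runif(1) < dc$p_pm,
    em_present = em, em_sites = em_sites
  )
}

rnorm_pos <- function(n, mean, sd, lower = 0.01) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Generate a synthetic staged cohort
#'
#' Samples labs and descriptors, derives the three stage labels with the
#' package's rule engines, then draws overall-survival times from the
#' configured proportional-hazards model: hazard = baseline x HR(DS Plus
#' stage) x HR(marrow Deauville >= 4) x HR(EMD), censored by an
#' independent uniform administrative-censoring time.  Fully
#' reproducible under a seed.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @param staging a [staging_config()] for the rule engines.
#' @return A cohort data frame (class `mm_cohort`) with the reference
#'   column layout plus lab, survival (`os_months`, `os_event`) and flag
#'   (`bm_ge4`, `emd`) columns.  Latent ground truth (uncensored event
#'   time, censoring time, true hazard ratio) is attached as the
#'   `"truth"` attribute.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20), seed = 1)
#' table(collapse_stage(cohort$stage_dsplus))
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            staging = staging_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(config$n_patients)
  lc <- config$labs
  sc <- config$survival

  if (n == 0L) {
    cohort <- empty_cohort()
    attr(cohort, "truth") <- data.frame(patient_id = integer(),
                                        event_time = numeric(),
                                        censor_time = numeric(),
                                        hazard_ratio = numeric())
    return(cohort)
  }

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(23, 10) / 33)
  age <- round(pmin(pmax(stats::rnorm(n, 60, 10), 30), 90))
  type <- sample(names(lc$type_probs), n, replace = TRUE,
                 prob = lc$type_probs)

  hb <- rnorm_pos(n, lc$hemoglobin_mean, lc$hemoglobin_sd)
  ca <- rnorm_pos(n, lc$calcium_mean, lc$calcium_sd)
  alb <- rnorm_pos(n, lc$albumin_mean, lc$albumin_sd)
  b2m <- stats::rlnorm(n, lc$beta2m_meanlog, lc$beta2m_sdlog)
  high_cr <- stats::runif(n) < lc$creatinine_p_high
  creat <- ifelse(high_cr,
                  pmax(rnorm_pos(n, lc$creatinine_high_mean,
                                 lc$creatinine_high_sd), 2),
                  pmin(rnorm_pos(n, lc$creatinine_low_mean,
                                 lc$creatinine_low_sd), 1.9))
  ldh_el <- stats::runif(n) < lc$p_ldh_elevated
  hr_ca <- stats::runif(n) < lc$p_high_risk_ca
  igg <- ifelse(type == "IgG",
                stats::rlnorm(n, lc$igg_meanlog, lc$igg_sdlog), NA_real_)
  iga <- ifelse(type == "IgA",
                stats::rlnorm(n, lc$iga_meanlog, lc$iga_sdlog), NA_real_)
  bj <- ifelse(type == "Light chain",
               stats::rlnorm(n, lc$bence_jones_meanlog,
                             lc$bence_jones_sdlog), NA_real_)
  xray <- sample(c("normal_or_solitary", "intermediate", "advanced_lytic"),
                 n, replace = TRUE, prob = c(0.15, 0.25, 0.6))
  treatment <- sample(c("None", "Chemotherapy", "Chemotherapy + IMIDs",
                        "Chemotherapy + BMT", "Other"),
                      n, replace = TRUE, prob = c(11, 7, 9, 4, 2) / 33)

  descriptors <- replicate(n, random_descriptor(config$descriptor),
                           simplify = FALSE)

  dss <- character(n); riss <- character(n); dsp <- character(n)
  bm_ge4 <- logical(n); emd <- logical(n)
  for (i in seq_len(n)) {
    labs <- lab_panel(
      hemoglobin = hb[i], serum_calcium = ca[i], igg = igg[i],
      iga = iga[i], bence_jones = bj[i], creatinine = creat[i],
      albumin = alb[i], beta2m = b2m[i], ldh_elevated = ldh_el[i],
      high_risk_cytogenetics = hr_ca[i], xray_bone_category = xray[i])
    dss[i] <- stage_label(stage_dss(labs, staging))
    riss[i] <- stage_label(stage_riss(labs, staging))
    a <- stage_dsplus(descriptors[[i]], labs, staging)
    dsp[i] <- stage_label(a)
    bm_ge4[i] <- descriptors[[i]]$bm_score >= 4L
    emd[i] <- suppressMessages(em_positive(descriptors[[i]]))
  }

  stage_num <- match(collapse_stage(dsp), STAGES)
  hr <- c(1, sc$hr_stage_ii, sc$hr_stage_iii)[stage_num] *
    ifelse(bm_ge4, sc$hr_bm_ge4, 1) *
    ifelse(emd, sc$hr_emd, 1)
  lambda0 <- log(2) / sc$median_stage_i
  u <- stats::runif(n)
  event_time <- if (sc$baseline == "exponential") {
    -log(u) / (lambda0 * hr)
  } else {
    (-log(u) / (lambda0 * hr))^(1 / sc$weibull_shape)
  }
  censor_time <- stats::runif(n, 0, sc$censor_window_months)
  os_months <- pmin(event_time, censor_time)
  os_event <- event_time <= censor_time

  cohort <- data.frame(
    patient_id = seq_len(n), sex = sex, age = age, myeloma_type = type,
    impetus = vapply(descriptors, serialize_impetus, ""),
    stage_dss = dss, stage_dsplus = dsp, stage_riss = riss,
    treatment = treatment,
    hemoglobin = hb, serum_calcium = ca, igg = igg, iga = iga,
    bence_jones = bj, creatinine = creat, albumin = alb, beta2m = b2m,
    ldh_elevated = ldh_el, high_risk_cytogenetics = hr_ca,
    xray_bone_category = xray,
    bm_ge4 = bm_ge4, emd = emd,
    os_months = os_months, os_event = os_event,
    stringsAsFactors = FALSE
  )
  cohort <- as_mm_cohort(cohort,
                         provenance = "synthetic cohort (generate_cohort)")
  attr(cohort, "truth") <- data.frame(
    patient_id = seq_len(n), event_time = event_time,
    censor_time = censor_time, hazard_ratio = hr,
    linear_predictor = log(hr))
  cohort
}
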
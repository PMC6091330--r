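#' @title Myeloma staging rule engines
#' @description
#' Three-stage classification of newly diagnosed multiple myeloma by
#' three systems: the Durie-Salmon staging system (DSS; hemoglobin,
#' calcium, skeletal radiography, M-component, renal function), the
#' Revised International Staging System (RISS; beta-2-microglobulin,
#' albumin, LDH, high-risk cytogenetics), and Durie-Salmon Plus
#' (focal-lesion burden and diffuse marrow disease read from FDG-PET/CT
#' via IMPeTUs, with a renal/extramedullary A/B subgroup).  All
#' thresholds live in [staging_config()] and every DS Plus call can emit
#' the rule trace it used.
#' @name staging-rules
NULL

#' Laboratory and cytogenetic panel for staging
#'
#' Collects the serum values and cytogenetic flags the DSS and RISS rules
#' consume.  Units follow clinical convention: hemoglobin and albumin
#' g/dL, calcium and creatinine mg/dL, beta-2-microglobulin mg/L, LDH
#' U/L, immunoglobulins g/dL, Bence Jones protein g/24h.  Fields a rule
#' set does not need may be left `NA`; the engines error if a field they
#' require is missing.
#'
#' @param hemoglobin,serum_calcium,creatinine,albumin,beta2m,ldh serum
#'   values (see above for units).
#' @param igg,iga,bence_jones M-component production rates; supply only
#'   those relevant to the myeloma type (nonsecretory disease leaves all
#'   three `NA`).
#' @param ldh_elevated logical, LDH above the local upper reference
#'   limit.
#' @param high_risk_cytogenetics logical, any of t(4;14), t(14;16),
#'   del(17p).
#' @param xray_bone_category skeletal-survey reading:
#'   `"normal_or_solitary"`, `"intermediate"`, or `"advanced_lytic"`.
#' @return An object of class `lab_panel`.
#' @export
lab_panel <- function(hemoglobin = NA_real_,
                      serum_calcium = NA_real_,
                      igg = NA_real_,
                      iga = NA_real_,
                      bence_jones = NA_real_,
                      creatinine = NA_real_,
                      albumin = NA_real_,
                      beta2m = NA_real_,
                      ldh = NA_real_,
                      ldh_elevated = NA,
                      high_risk_cytogenetics = NA,
                      xray_bone_category = NA_character_) {
  num <- list(hemoglobin = hemoglobin, serum_calcium = serum_calcium,
              igg = igg, iga = iga, bence_jones = bence_jones,
              creatinine = creatinine, albumin = albumin,
              beta2m = beta2m, ldh = ldh)
  for (nm in names(num)) {
    v <- num[[nm]]
    stopifnot(length(v) == 1L)
    if (!is.na(v) && (!is.numeric(v) || v < 0)) {
      stop(nm, " must be a nonnegative number", call. = FALSE)
    }
  }
  if (!is.na(xray_bone_category) &&
      !xray_bone_category %in% c("normal_or_solitary", "intermediate",
                                 "advanced_lytic")) {
    stop("unknown xray_bone_category: ", xray_bone_category, call. = FALSE)
  }
  structure(
    c(lapply(num, as.numeric),
      list(ldh_elevated = as.logical(ldh_elevated),
           high_risk_cytogenetics = as.logical(high_risk_cytogenetics),
           xray_bone_category = as.character(xray_bone_category))),
    class = "lab_panel"
  )
}

#' Default staging thresholds and rule tables
#'
#' Returns the full configuration the three engines read, as a nested
#' list that can be edited in R or overridden from a YAML file (see
#' [load_config()]).  Notable entries:
#'
#' * `dss$calcium_iii`: the stage-III hypercalcemia trigger is serum
#'   calcium **greater than** 12 mg/dL.  Some printed renditions of the
#'   DSS criteria carry the comparison in the opposite direction, which
#'   would make stage III near-universal; the direction is exposed here
#'   (`dss$calcium_iii_direction`) precisely so it can be audited.
#' * `dsplus$focal_stage` / `dsplus$diffuse_stage`: the default mapping
#'   from IMPeTUs focal count grade and bone-marrow Deauville score to
#'   the DS Plus stage contributed by each axis.  Focal grades 1-2
#'   (up to 3 lesions) map to stage I, grade 3 (4-10 lesions) to II,
#'   grade 4 (>10) to III; a focal component whose hottest lesion is not
#'   PET-positive (Deauville < 4) is demoted one stage.  Diffuse disease:
#'   marrow Deauville <= 2 is mild (I), 3 moderate (II), >= 4 severe
#'   (III).
#'
#' @param overrides optional named list merged over the defaults
#'   (recursively, by name).
#' @return A nested configuration list with components `dss`, `riss`,
#'   `dsplus`.
#' @export
staging_config <- function(overrides = NULL) {
  cfg <- list(
    dss = list(
      hb_i = 10,            # stage I needs Hb > this
      calcium_i = 10.5,     # stage I needs Ca <= this
      igg_i = 5, iga_i = 3, bence_jones_i = 4,
      hb_iii = 8.5,         # stage III if Hb < this
      calcium_iii = 12,
      calcium_iii_direction = "greater",   # "greater" or "less"
      igg_iii = 7, iga_iii = 5, bence_jones_iii = 12,
      creatinine_b = 2.0    # subgroup B if creatinine >= this
    ),
    riss = list(
      albumin_i = 3.5, beta2m_i = 3.5, beta2m_iii = 5.5
    ),
    dsplus = list(
      focal_stage = c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 3L),
      demote_below_score = 4L,  # demote focal component if hottest < this
      diffuse_stage = c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 3L, "5" = 3L),
      creatinine_b = 2.0        # subgroup B if creatinine > this, or EMD
    )
  )
  modify_defaults(cfg, overrides)
}

modify_defaults <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

STAGES <- c("I", "II", "III")

new_stage_assignment <- function(system, stage, subgroup = "none",
                                 trace = NULL) {
  stopifnot(system %in% c("DSS", "RISS", "DSPLUS"),
            stage %in% STAGES,
            subgroup %in% c("A", "B", "none"))
  if (system == "RISS" && subgroup != "none") {
    stop("RISS has no A/B subgroup", call. = FALSE)
  }
  structure(list(system = system, stage = stage, subgroup = subgroup,
                 trace = trace),
            class = "stage_assignment")
}

#' @export
format.stage_assignment <- function(x, ...) stage_label(x)

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("<%s stage> %s\n", x$system, stage_label(x)))
  if (!is.null(x$trace)) cat(paste0("  - ", x$trace, "\n"), sep = "")
  invisible(x)
}

#' Stage labels as printed in clinical tables
#'
#' `stage_label()` renders a [stage_assignment][stage_dss] as the compact
#' label used in publications (`"IIIB"`, `"IA"`, `"III"`).
#' `parse_stage_label()` inverts it; `collapse_stage()` strips the A/B
#' subgroup suffix, the form under which the three systems are compared.
#'
#' @param x a `stage_assignment` (for `stage_label`) or character vector
#'   of labels (for the others).
#' @return `stage_label`: a string.  `parse_stage_label`: a data frame
#'   with columns `stage` and `subgroup`.  `collapse_stage`: a character
#'   vector over `"I"/"II"/"III"`.
#' @export
stage_label <- function(x) {
  stopifnot(inherits(x, "stage_assignment"))
  paste0(x$stage, if (x$subgroup == "none") "" else x$subgroup)
}

#' @rdname stage_label
#' @export
parse_stage_label <- function(x) {
  m <- regmatches(x, regexec("^(III|II|I)([AB]?)$", as.character(x)))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    stop("unparseable stage label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    stage = vapply(m, `[`, "", 2L),
    subgroup = ifelse(vapply(m, `[`, "", 3L) == "", "none",
                      vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname stage_label
#' @export
collapse_stage <- function(x) parse_stage_label(x)$stage

require_labs <- function(labs, fields, system) {
  stopifnot(inherits(labs, "lab_panel"))
  for (f in fields) {
    if (is.na(labs[[f]])) {
      stop(system, " staging requires lab field '", f, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Durie-Salmon stage from a laboratory panel
#'
#' Stage I requires *all* low-burden conditions (hemoglobin > 10 g/dL,
#' normal calcium <= 10.5 mg/dL, normal skeletal survey or a solitary
#' plasmacytoma, low M-component: IgG < 5 g/dL, IgA < 3 g/dL, Bence
#' Jones < 4 g/24h).  Stage III fires on *any* high-burden condition
#' (hemoglobin < 8.5 g/dL, calcium > 12 mg/dL, advanced lytic bone
#' disease, IgG > 7 g/dL, IgA > 5 g/dL, Bence Jones > 12 g/24h).
#' Stage II is neither I nor III.  Subgroup A/B splits on serum
#' creatinine below / at-or-above 2.0 mg/dL.  M-component clauses that
#' reference an isotype the panel does not carry are treated as not
#' triggered (and as satisfied for stage I), so light-chain and
#' nonsecretory disease stage on the remaining criteria.
#'
#' @param labs a [lab_panel()]; requires `hemoglobin`, `serum_calcium`,
#'   `creatinine` and `xray_bone_category`.
#' @param config a [staging_config()] list.
#' @return A `stage_assignment` with system `"DSS"`.
#' @export
stage_dss <- function(labs, config = staging_config()) {
  require_labs(labs, c("hemoglobin", "serum_calcium", "creatinine"), "DSS")
  if (is.na(labs$xray_bone_category)) {
    stop("DSS staging requires lab field 'xray_bone_category'",
         call. = FALSE)
  }
  cf <- config$dss
  ca_iii <- if (identical(cf$calcium_iii_direction, "less")) {
    labs$serum_calcium < cf$calcium_iii
  } else {
    labs$serum_calcium > cf$calcium_iii
  }
  m_low <- (is.na(labs$igg) || labs$igg < cf$igg_i) &&
    (is.na(labs$iga) || labs$iga < cf$iga_i) &&
    (is.na(labs$bence_jones) || labs$bence_jones < cf$bence_jones_i)
  m_high <- (!is.na(labs$igg) && labs$igg > cf$igg_iii) ||
    (!is.na(labs$iga) && labs$iga > cf$iga_iii) ||
    (!is.na(labs$bence_jones) && labs$bence_jones > cf$bence_jones_iii)
  is_iii <- labs$hemoglobin < cf$hb_iii || ca_iii ||
    labs$xray_bone_category == "advanced_lytic" || m_high
  is_i <- labs$hemoglobin > cf$hb_i &&
    labs$serum_calcium <= cf$calcium_i &&
    labs$xray_bone_category == "normal_or_solitary" && m_low
  stage <- if (is_iii) "III" else if (is_i) "I" else "II"
  sub <- if (labs$creatinine < cf$creatinine_b) "A" else "B"
  new_stage_assignment("DSS", stage, sub)
}

#' Revised International Staging System stage
#'
#' Stage I: ISS stage I (albumin >= 3.5 g/dL and beta-2-microglobulin
#' < 3.5 mg/L) with normal LDH and no high-risk cytogenetics.  Stage
#' III: ISS stage III (beta-2-microglobulin > 5.5 mg/L) with elevated
#' LDH or high-risk cytogenetics.  Stage II: neither.
#'
#' @param labs a [lab_panel()]; requires `albumin`, `beta2m`,
#'   `ldh_elevated`, `high_risk_cytogenetics`.
#' @param config a [staging_config()] list.
#' @return A `stage_assignment` with system `"RISS"` (no subgroup).
#' @examples
#' stage_riss(lab_panel(albumin = 3.2, beta2m = 6.08, ldh_elevated = TRUE,
#'                      high_risk_cytogenetics = FALSE))
#' @export
stage_riss <- function(labs, config = staging_config()) {
  require_labs(labs, c("albumin", "beta2m"), "RISS")
  if (is.na(labs$ldh_elevated)) {
    stop("RISS staging requires lab field 'ldh_elevated'", call. = FALSE)
  }
  if (is.na(labs$high_risk_cytogenetics)) {
    stop("RISS staging requires lab field 'high_risk_cytogenetics'",
         call. = FALSE)
  }
  cf <- config$riss
  is_i <- labs$albumin >= cf$albumin_i && labs$beta2m < cf$beta2m_i &&
    !labs$ldh_elevated && !labs$high_risk_cytogenetics
  is_iii <- labs$beta2m > cf$beta2m_iii &&
    (labs$ldh_elevated || labs$high_risk_cytogenetics)
  stage <- if (is_iii) "III" else if (is_i) "I" else "II"
  new_stage_assignment("RISS", stage)
}

#' Durie-Salmon Plus stage from an IMPeTUs descriptor
#'
#' Combines a focal and a diffuse disease axis, each mapped to a stage by
#' the configurable rule table (see [staging_config()]), and takes the
#' worse of the two.  The focal axis reads the IMPeTUs focal count grade
#' (a report with no `F` token counts as grade 1, i.e. no focal lesions)
#' and is demoted one stage when its hottest lesion is not PET-positive
#' (Deauville score below 4, per [bone_positive()]).  The diffuse axis
#' reads the bone-marrow Deauville score.  Subgroup B is assigned on
#' renal impairment (creatinine > 2.0 mg/dL) and/or extramedullary
#' disease ([em_positive()]); otherwise A.
#'
#' The decision path is returned in the assignment's `trace` field so
#' every staging call can be audited.
#'
#' @param d an [impetus_descriptor()].
#' @param labs a [lab_panel()] (only `creatinine` is read) or a single
#'   creatinine value in mg/dL; `NA` is allowed and then only EMD can
#'   trigger subgroup B.
#' @param config a [staging_config()] list.
#' @return A `stage_assignment` with system `"DSPLUS"` and a rule trace.
#' @examples
#' d <- parse_impetus("BM(5)A, F4.S.SP.ExtraSP(5), L4, EM.EN(4)")
#' stage_dsplus(d, labs = 1.1)
#' @export
stage_dsplus <- function(d, labs = NA_real_, config = staging_config()) {
  stopifnot(inherits(d, "impetus_descriptor"))
  creat <- if (inherits(labs, "lab_panel")) labs$creatinine else {
    stopifnot(length(labs) == 1L)
    as.numeric(labs)
  }
  cf <- config$dsplus
  if (is.na(d$focal_grade) && is.na(d$bm_score)) {
    stop("descriptor carries neither focal nor bone-marrow information",
         call. = FALSE)
  }
  trace <- character()

  fg <- if (is.na(d$focal_grade)) 1L else d$focal_grade
  focal <- unname(cf$focal_stage[as.character(fg)])
  trace <- c(trace, sprintf("focal grade %d -> stage %s%s", fg,
                            STAGES[focal],
                            if (is.na(d$focal_grade))
                              " (no F token, counted as grade 1)" else ""))
  if (fg > 1L &&
      (is.na(d$focal_score) || d$focal_score < cf$demote_below_score)) {
    demoted <- max(focal - 1L, 1L)
    trace <- c(trace, sprintf(
      "focal component not PET-positive (score %s < %d): demoted %s -> %s",
      ifelse(is.na(d$focal_score), "absent", d$focal_score),
      cf$demote_below_score, STAGES[focal], STAGES[demoted]))
    focal <- demoted
  }

  diffuse <- unname(cf$diffuse_stage[as.character(d$bm_score)])
  trace <- c(trace, sprintf("diffuse marrow Deauville %d -> stage %s",
                            d$bm_score, STAGES[diffuse]))

  stage <- max(focal, diffuse)
  trace <- c(trace, sprintf("stage = max(focal %s, diffuse %s) = %s",
                            STAGES[focal], STAGES[diffuse], STAGES[stage]))

  emd <- em_positive(d)
  renal <- !is.na(creat) && creat > cf$creatinine_b
  sub <- if (renal || emd) "B" else "A"
  trace <- c(trace, sprintf(
    "subgroup %s (creatinine %s mg/dL, EMD %s)", sub,
    ifelse(is.na(creat), "unknown", format(creat)),
    if (emd) "positive" else "negative"))

  new_stage_assignment("DSPLUS", STAGES[stage], sub, trace = trace)
}

#' Compare engine-derived stages against a reference column
#'
#' Tabulates per-patient agreement between stages assigned by a rule
#' engine and stages recorded in a cohort (for instance a published
#' table), listing every mismatch together with the engine's rule trace.
#' Inputs are never modified.
#'
#' @param derived list of `stage_assignment`s or character labels.
#' @param printed character vector of reference labels (same length and
#'   patient order).
#' @param ids optional patient identifiers.
#' @return A list of class `agreement_report`: `table` (patient, derived,
#'   printed, match), `agreement` (fraction of matching collapsed
#'   stages), `mismatches` (subset of `table` with traces attached).
#' @export
agreement_report <- function(derived, printed, ids = NULL) {
  if (is.list(derived) && all(vapply(derived, inherits, TRUE,
                                     "stage_assignment"))) {
    traces <- lapply(derived, `[[`, "trace")
    derived <- vapply(derived, stage_label, "")
  } else {
    derived <- as.character(derived)
    traces <- vector("list", length(derived))
  }
  printed <- as.character(printed)
  if (length(derived) != length(printed)) {
    stop("derived and printed stage vectors differ in length (",
         length(derived), " vs ", length(printed), ")", call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_along(derived)
  match_ <- collapse_stage(derived) == collapse_stage(printed)
  tab <- data.frame(patient = ids, derived = derived, printed = printed,
                    match = match_, stringsAsFactors = FALSE)
  mism <- tab[!tab$match, , drop = FALSE]
  mism$trace <- traces[!tab$match]
  structure(
    list(table = tab,
         agreement = if (nrow(tab)) mean(match_) else NA_real_,
         mismatches = mism),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Stage agreement: %d/%d (%.1f%%)\n",
              sum(x$table$match), nrow(x$table), 100 * x$agreement))
  if (nrow(x$mismatches)) {
    cat("Mismatches:\n")
    print(x$mismatches[c("patient", "derived", "printed")],
          row.names = FALSE)
  }
  invisible(x)
}
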
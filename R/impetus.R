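#' @title IMPeTUs descriptor grammar
#' @description
#' IMPeTUs (Italian Myeloma criteria for PET USe) is a standardized
#' descriptive notation for whole-body FDG-PET/CT findings in multiple
#' myeloma.  A report string is a comma-separated token list, e.g.
#' `"BM(3), F3.SP.ExtraSP(4), L2, PM, EM.N(2)"`:
#'
#' * `BM(k)` — diffuse bone-marrow uptake graded `k` on the Deauville
#'   5-point scale, optionally suffixed `A` (appendicular skeleton
#'   involvement flag, stored but not interpreted);
#' * `F<g>[.sites](k)` — focal bone lesions, count grade `g` in 1–4
#'   (1 = none, 2 = 1–3, 3 = 4–10, 4 = >10), sites among `S` (skull),
#'   `SP` (spine), `ExtraSP` (outside the spine), hottest-lesion
#'   Deauville score `k`;
#' * `L<g>` — how many of the focal lesions are lytic, same count grades;
#' * `Fr` — at least one fracture;
#' * `PM` — paramedullary disease (soft-tissue extension through cortex);
#' * `EM[.site(k)]+` — extramedullary disease, sites `N` (nodal) and
#'   `EN` (extranodal), each with an optional Deauville score.
#'
#' Deauville scores grade uptake against reference regions: 1 no uptake,
#' 2 \eqn{\le} mediastinum, 3 \eqn{\le} liver, 4 moderately > liver,
#' 5 markedly > liver.
#' @name impetus-grammar
NULL

IMPETUS_SITES <- c(S = "skull", SP = "spine", ExtraSP = "extraspine")
EM_SITES <- c(N = "nodal", EN = "extranodal")

#' Construct an IMPeTUs descriptor record
#'
#' Builds a validated structured record of PET/CT findings.  Most users
#' will obtain records from [parse_impetus()] instead; the constructor is
#' the entry point for programmatic generation (see
#' [generate_descriptor()]).
#'
#' @param bm_score Deauville score (1-5) of diffuse bone-marrow uptake.
#' @param bm_appendicular logical; `A` suffix on the BM token.
#' @param focal_grade focal-lesion count grade 1-4, or `NA` when the
#'   report carries no focal (`F`) token.
#' @param focal_sites character subset of
#'   `c("skull", "spine", "extraspine")`.
#' @param focal_score Deauville score of the hottest focal lesion, or `NA`.
#' @param lytic_grade lytic-lesion count grade 1-4, or `NA`.
#' @param fracture,paramedullary,em_present logicals for the `Fr`, `PM`
#'   and `EM` tokens.
#' @param em_sites data frame with columns `site` (`"nodal"` /
#'   `"extranodal"`) and `score` (Deauville score or `NA`); must be empty
#'   unless `em_present`.
#' @param raw the originating report string, or `NA` for constructed
#'   records.
#' @return An object of class `impetus_descriptor`.
#' @seealso [parse_impetus()], [serialize_impetus()]
#' @export
impetus_descriptor <- function(bm_score,
                               bm_appendicular = FALSE,
                               focal_grade = NA_integer_,
                               focal_sites = character(),
                               focal_score = NA_integer_,
                               lytic_grade = NA_integer_,
                               fracture = FALSE,
                               paramedullary = FALSE,
                               em_present = FALSE,
                               em_sites = empty_em_sites(),
                               raw = NA_character_) {
  check_score(bm_score, "bm_score")
  stopifnot(is.logical(bm_appendicular), length(bm_appendicular) == 1L)
  if (!is.na(focal_grade)) check_grade(focal_grade, "focal_grade")
  focal_sites <- canonical_sites(focal_sites)
  if (!is.na(focal_score)) {
    if (is.na(focal_grade)) {
      stop("focal_score requires focal_grade", call. = FALSE)
    }
    check_score(focal_score, "focal_score")
  }
  if (length(focal_sites) > 0L && is.na(focal_grade)) {
    stop("focal_sites require focal_grade", call. = FALSE)
  }
  if (!is.na(lytic_grade)) check_grade(lytic_grade, "lytic_grade")
  em_sites <- as_em_sites(em_sites)
  if (!em_present && nrow(em_sites) > 0L) {
    stop("em_sites must be empty when em_present is FALSE", call. = FALSE)
  }
  if (em_present && nrow(em_sites) == 0L) {
    stop("em_present requires at least one EM site", call. = FALSE)
  }
  structure(
    list(
      bm_score = as.integer(bm_score),
      bm_appendicular = isTRUE(bm_appendicular),
      focal_grade = as.integer(focal_grade),
      focal_sites = focal_sites,
      focal_score = as.integer(focal_score),
      lytic_grade = as.integer(lytic_grade),
      fracture = isTRUE(fracture),
      paramedullary = isTRUE(paramedullary),
      em_present = isTRUE(em_present),
      em_sites = em_sites,
      raw = as.character(raw)
    ),
    class = "impetus_descriptor"
  )
}

empty_em_sites <- function() {
  data.frame(site = character(), score = integer(),
             stringsAsFactors = FALSE)
}

as_em_sites <- function(x) {
  if (is.null(x)) return(empty_em_sites())
  stopifnot(is.data.frame(x), all(c("site", "score") %in% names(x)))
  x <- data.frame(site = as.character(x$site),
                  score = as.integer(x$score),
                  stringsAsFactors = FALSE)
  bad <- !x$site %in% EM_SITES
  if (any(bad)) {
    stop("unknown EM site: ", paste(x$site[bad], collapse = ", "),
         call. = FALSE)
  }
  for (s in x$score[!is.na(x$score)]) check_score(s, "em site score")
  rownames(x) <- NULL
  x
}

canonical_sites <- function(sites) {
  if (length(sites) == 0L) return(character())
  sites <- as.character(sites)
  bad <- !sites %in% IMPETUS_SITES
  if (any(bad)) {
    stop("unknown focal site: ", paste(sites[bad], collapse = ", "),
         call. = FALSE)
  }
  # canonical order: skull, spine, extraspine
  unname(IMPETUS_SITES[IMPETUS_SITES %in% unique(sites)])
}

check_score <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x) ||
      x < 1L || x > 5L) {
    stop(what, " must be a Deauville score in 1..5 (got ",
         deparse(x), ")", call. = FALSE)
  }
  invisible(TRUE)
}

check_grade <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x) ||
      x < 1L || x > 4L) {
    stop(what, " must be a count grade in 1..4 (got ",
         deparse(x), ")", call. = FALSE)
  }
  invisible(TRUE)
}

parse_error <- function(token, offset, why) {
  stop(sprintf("malformed IMPeTUs token '%s' at character %d: %s",
               token, offset, why), call. = FALSE)
}

#' Parse an IMPeTUs descriptor string
#'
#' Tokenizes and validates a comma-separated IMPeTUs report string.
#' Whitespace around commas is ignored; token names are case-sensitive.
#' Unknown or malformed tokens are rejected with an error naming the
#' offending token and its character offset -- staging must never run on
#' partially understood input.
#'
#' @param text a single non-empty IMPeTUs string, e.g.
#'   `"BM(3), F3.SP.ExtraSP(4), L2, PM, EM.N(2)"`.
#' @return An [impetus_descriptor()] record with `raw = text`.
#' @examples
#' d <- parse_impetus("BM(3), F3.SP.ExtraSP(4), L2, PM, EM.N(2)")
#' d$focal_sites
#' d$em_sites
#' @export
parse_impetus <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("IMPeTUs input must be a single non-empty string", call. = FALSE)
  }
  pieces <- strsplit(text, ",", fixed = TRUE)[[1]]
  # character offset (1-based) where each comma-separated piece starts
  starts <- c(1L, cumsum(nchar(pieces) + 1L)[-length(pieces)] + 1L)

  seen <- character()
  bm_score <- NA_integer_; bm_app <- FALSE
  focal_grade <- NA_integer_; focal_sites <- character()
  focal_score <- NA_integer_
  lytic_grade <- NA_integer_
  fracture <- FALSE; pm <- FALSE
  em_present <- FALSE; em_sites <- empty_em_sites()

  for (i in seq_along(pieces)) {
    tok <- trimws(pieces[i])
    off <- starts[i] + (nchar(pieces[i]) - nchar(trimws(pieces[i],
                                                        which = "left")))
    if (!nzchar(tok)) parse_error(pieces[i], starts[i], "empty token")
    kind <- token_kind(tok)
    if (is.na(kind)) parse_error(tok, off, "unknown token")
    if (kind %in% seen) parse_error(tok, off, paste0("duplicate ", kind,
                                                     " token"))
    seen <- c(seen, kind)
    if (kind == "BM") {
      m <- regmatches(tok, regexec("^BM\\(([0-9]+)\\)(A?)$", tok))[[1]]
      if (length(m) == 0L) parse_error(tok, off, "expected BM(score)[A]")
      sc <- as.integer(m[2])
      if (sc < 1L || sc > 5L) parse_error(tok, off,
                                          "Deauville score outside 1-5")
      bm_score <- sc
      bm_app <- nzchar(m[3])
    } else if (kind == "F") {
      parsed <- parse_focal_token(tok, off)
      focal_grade <- parsed$grade
      focal_sites <- parsed$sites
      focal_score <- parsed$score
    } else if (kind == "L") {
      m <- regmatches(tok, regexec("^L([0-9]+)$", tok))[[1]]
      if (length(m) == 0L) parse_error(tok, off, "expected L<grade>")
      g <- as.integer(m[2])
      if (g < 1L || g > 4L) parse_error(tok, off, "count grade outside 1-4")
      lytic_grade <- g
    } else if (kind == "Fr") {
      fracture <- TRUE
    } else if (kind == "PM") {
      pm <- TRUE
    } else if (kind == "EM") {
      em_present <- TRUE
      em_sites <- parse_em_token(tok, off)
    }
  }

  if (is.na(bm_score)) {
    stop("IMPeTUs string lacks the mandatory BM token: ", text,
         call. = FALSE)
  }
  impetus_descriptor(
    bm_score = bm_score, bm_appendicular = bm_app,
    focal_grade = focal_grade, focal_sites = focal_sites,
    focal_score = focal_score, lytic_grade = lytic_grade,
    fracture = fracture, paramedullary = pm,
    em_present = em_present, em_sites = em_sites,
    raw = text
  )
}

token_kind <- function(tok) {
  if (tok == "Fr") return("Fr")
  if (tok == "PM") return("PM")
  if (startsWith(tok, "BM")) return("BM")
  if (startsWith(tok, "EM")) return("EM")
  if (grepl("^F[0-9]", tok)) return("F")
  if (grepl("^L[0-9]", tok)) return("L")
  NA_character_
}

parse_focal_token <- function(tok, off) {
  m <- regmatches(
    tok,
    regexec("^F([0-9]+)((?:\\.(?:ExtraSP|SP|S))*)(?:\\(([0-9]+)\\))?$", tok)
  )[[1]]
  if (length(m) == 0L) {
    parse_error(tok, off, "expected F<grade>[.sites][(score)]")
  }
  g <- as.integer(m[2])
  if (g < 1L || g > 4L) parse_error(tok, off, "count grade outside 1-4")
  sites <- character()
  if (nzchar(m[3])) {
    abbr <- strsplit(sub("^\\.", "", m[3]), ".", fixed = TRUE)[[1]]
    if (anyDuplicated(abbr)) parse_error(tok, off, "duplicate site")
    sites <- unname(IMPETUS_SITES[abbr])
  }
  score <- NA_integer_
  if (!is.na(m[4]) && nzchar(m[4])) {
    score <- as.integer(m[4])
    if (score < 1L || score > 5L) {
      parse_error(tok, off, "Deauville score outside 1-5")
    }
  }
  list(grade = g, sites = sites, score = score)
}

# EM body: one or more site segments "N" / "EN", each optionally scored,
# separated by "." (the dot may be omitted right after a closing
# parenthesis, as printed in e.g. "EM.N(5)EN(4)").
parse_em_token <- function(tok, off) {
  body <- substring(tok, 3L)
  if (!nzchar(body)) parse_error(tok, off, "EM requires at least one site")
  sites <- character(); scores <- integer()
  pos <- 1L
  n <- nchar(body)
  expect_dot <- TRUE
  while (pos <= n) {
    if (substring(body, pos, pos) == ".") {
      pos <- pos + 1L
    } else if (expect_dot) {
      parse_error(tok, off, "expected '.' before EM site")
    }
    seg <- regmatches(
      substring(body, pos),
      regexec("^(EN|N)(?:\\(([0-9]+)\\))?", substring(body, pos))
    )[[1]]
    if (length(seg) == 0L || !nzchar(seg[1])) {
      parse_error(tok, off, "expected EM site N or EN")
    }
    sites <- c(sites, unname(EM_SITES[seg[2]]))
    sc <- NA_integer_
    if (!is.na(seg[3]) && nzchar(seg[3])) {
      sc <- as.integer(seg[3])
      if (sc < 1L || sc > 5L) parse_error(tok, off,
                                          "Deauville score outside 1-5")
    }
    scores <- c(scores, sc)
    # a dot is optional immediately after "(score)"
    expect_dot <- is.na(sc)
    pos <- pos + nchar(seg[1])
  }
  if (length(sites) == 0L) parse_error(tok, off,
                                       "EM requires at least one site")
  if (anyDuplicated(sites)) parse_error(tok, off, "duplicate EM site")
  data.frame(site = sites, score = scores, stringsAsFactors = FALSE)
}

#' Serialize a descriptor back to its canonical IMPeTUs string
#'
#' Emits tokens in canonical order (`BM`, `F`, `L`, `Fr`, `PM`, `EM`) with
#' sites in skull/spine/extraspine order.  Serialization is the inverse of
#' [parse_impetus()]: the emitted string re-parses to a record identical
#' to the input (up to the stored `raw` text).
#'
#' @param d an [impetus_descriptor()].
#' @return A single IMPeTUs string.
#' @examples
#' serialize_impetus(parse_impetus("BM(2), F2.SP(4), L2"))
#' @export
serialize_impetus <- function(d) {
  stopifnot(inherits(d, "impetus_descriptor"))
  abbr <- names(IMPETUS_SITES)[match(d$focal_sites, IMPETUS_SITES)]
  toks <- sprintf("BM(%d)%s", d$bm_score, if (d$bm_appendicular) "A" else "")
  if (!is.na(d$focal_grade)) {
    f <- sprintf("F%d", d$focal_grade)
    if (length(abbr)) f <- paste0(f, ".", paste(abbr, collapse = "."))
    if (!is.na(d$focal_score)) f <- sprintf("%s(%d)", f, d$focal_score)
    toks <- c(toks, f)
  }
  if (!is.na(d$lytic_grade)) toks <- c(toks, sprintf("L%d", d$lytic_grade))
  if (d$fracture) toks <- c(toks, "Fr")
  if (d$paramedullary) toks <- c(toks, "PM")
  if (d$em_present) {
    em_abbr <- names(EM_SITES)[match(d$em_sites$site, EM_SITES)]
    segs <- ifelse(is.na(d$em_sites$score), em_abbr,
                   sprintf("%s(%d)", em_abbr, d$em_sites$score))
    toks <- c(toks, paste0("EM.", paste(segs, collapse = ".")))
  }
  paste(toks, collapse = ", ")
}

#' @export
format.impetus_descriptor <- function(x, ...) serialize_impetus(x)

#' @export
print.impetus_descriptor <- function(x, ...) {
  cat("<impetus_descriptor> ", serialize_impetus(x), "\n", sep = "")
  invisible(x)
}

#' Compare two descriptor records for semantic equality
#'
#' Equality of all parsed fields; the stored `raw` strings are ignored, so
#' a record and the re-parse of its serialization compare equal.
#'
#' @param a,b [impetus_descriptor()] records.
#' @return `TRUE` or `FALSE`.
#' @export
impetus_equal <- function(a, b) {
  stopifnot(inherits(a, "impetus_descriptor"),
            inherits(b, "impetus_descriptor"))
  strip <- function(d) d[setdiff(names(d), "raw")]
  isTRUE(all.equal(strip(unclass(a)), strip(unclass(b))))
}

#' Extramedullary-disease positivity
#'
#' A patient is EMD-positive when extramedullary lesions are present and
#' the highest per-site Deauville score is 4 or 5 (uptake above liver).
#' Sites reported without a score are non-assessable; by default they do
#' not count towards positivity and a message is emitted.
#'
#' @param d an [impetus_descriptor()].
#' @param missing_score policy for EM sites without a score:
#'   `"negative"` (default; treat as non-assessable) or `"error"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' em_positive(parse_impetus("BM(3), PM, EM.N(2)"))      # FALSE
#' em_positive(parse_impetus("BM(4), EM.N(5)EN(4)"))     # TRUE
#' @export
em_positive <- function(d, missing_score = c("negative", "error")) {
  stopifnot(inherits(d, "impetus_descriptor"))
  missing_score <- match.arg(missing_score)
  if (!d$em_present) return(FALSE)
  scores <- d$em_sites$score
  if (anyNA(scores)) {
    if (missing_score == "error") {
      stop("EM site without a Deauville score: ", serialize_impetus(d),
           call. = FALSE)
    }
    message("EM site without a Deauville score treated as non-assessable: ",
            serialize_impetus(d))
    scores <- scores[!is.na(scores)]
  }
  length(scores) > 0L && max(scores) >= 4L
}

#' Focal bone-lesion positivity
#'
#' Positive bone lesions are focal lesions with a Deauville score of 4 or
#' more, or diffuse lytic lesions 0.5-1 cm in size with a Deauville score
#' of 3 or more.  IMPeTUs strings carry no lesion size, so the size gate
#' can only fire when `lesion_size_cm` is supplied alongside the
#' descriptor.
#'
#' @param d an [impetus_descriptor()].
#' @param lesion_size_cm optional lesion size in cm for the
#'   small-lytic-lesion rule.
#' @return `TRUE` or `FALSE`; `FALSE` when the descriptor has no scored
#'   focal component.
#' @export
bone_positive <- function(d, lesion_size_cm = NULL) {
  stopifnot(inherits(d, "impetus_descriptor"))
  if (is.na(d$focal_score)) return(FALSE)
  if (d$focal_score >= 4L) return(TRUE)
  if (!is.null(lesion_size_cm) && !is.na(lesion_size_cm) &&
      lesion_size_cm >= 0.5 && lesion_size_cm <= 1 &&
      d$focal_score >= 3L) {
    return(TRUE)
  }
  FALSE
}

#' Lesion-count semantics of IMPeTUs grades
#'
#' The focal (`F`) and lytic (`L`) count grades map to lesion-count
#' ranges: grade 1 = no lesions, 2 = 1-3, 3 = 4-10, 4 = more than 10.
#' Shipped as an editable table so local reading conventions can be
#' swapped in.
#'
#' @return A list with `focal_grade_to_count_range` and
#'   `lytic_grade_to_count_range` (matrices with `min`/`max` columns,
#'   `max = Inf` for open-ended) and `deauville_reference_text`.
#' @export
grade_semantics <- function() {
  rng <- cbind(min = c(0, 1, 4, 11), max = c(0, 3, 10, Inf))
  rownames(rng) <- as.character(1:4)
  list(
    focal_grade_to_count_range = rng,
    lytic_grade_to_count_range = rng,
    deauville_reference_text = c(
      "1" = "no uptake",
      "2" = "uptake <= mediastinum",
      "3" = "uptake > mediastinum but <= liver",
      "4" = "uptake > liver + 10%",
      "5" = "uptake markedly > liver"
    )
  )
}
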
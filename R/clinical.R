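#' Validate clinical visit components
#'
#' Checks the five components of a 28-joint disease-activity assessment.
#' All arguments are vectorised and recycled to a common length.
#'
#' @param tjc28,sjc28 tender / swollen joint counts, integers in 0--28.
#' @param crp_mg_l C-reactive protein in mg/L (>= 0).
#' @param pga_cm,ega_cm patient / evaluator global assessment on a 0--10 cm
#'   visual-analogue scale. `ega_cm` may be `NULL` when not needed.
#' @return invisibly `TRUE`; signals an error naming the offending field
#'   otherwise.
#' @keywords internal
validate_visit <- function(tjc28, sjc28, crp_mg_l, pga_cm, ega_cm = NULL) {
  chk <- function(x, lo, hi, field, integer = FALSE) {
    if (any(!is.finite(x))) {
      stop("non-finite value in field '", field, "'", call. = FALSE)
    }
    bad <- which(x < lo | x > hi)
    if (length(bad)) {
      stop("field '", field, "' out of range [", lo, ", ", hi, "] at row ",
           bad[1L], " (value ", x[bad[1L]], ")", call. = FALSE)
    }
    if (integer && any(x != round(x))) {
      stop("field '", field, "' must be integer-valued", call. = FALSE)
    }
  }
  chk(tjc28, 0, 28, "tjc28", integer = TRUE)
  chk(sjc28, 0, 28, "sjc28", integer = TRUE)
  chk(crp_mg_l, 0, Inf, "crp_mg_l")
  chk(pga_cm, 0, 10, "pga_cm")
  if (!is.null(ega_cm)) chk(ega_cm, 0, 10, "ega_cm")
  invisible(TRUE)
}

#' DAS28-CRP composite disease-activity score
#'
#' Four-variable disease activity score in 28 joints using CRP:
#' \deqn{0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.36\ln(CRP + 1) +
#'   0.014\,GH + 0.96}
#' where CRP is in mg/L and GH is the patient global assessment converted to
#' a 0--100 mm scale internally (the input is in cm).
#'
#' @inheritParams validate_visit
#' @return numeric vector of scores (each >= 0.96).
#' @examples
#' das28_crp(0, 0, 0, 0)      # intercept only: 0.96
#' das28_crp(4, 4, 10, 5)
#' @export
das28_crp <- function(tjc28, sjc28, crp_mg_l, pga_cm) {
  validate_visit(tjc28, sjc28, crp_mg_l, pga_cm)
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.36 * log(crp_mg_l + 1) +
    0.014 * (pga_cm * 10) + 0.96
}

#' Simplified and clinical disease activity indices
#'
#' SDAI is the plain sum of tender and swollen 28-joint counts, patient and
#' evaluator global assessments (cm) and CRP in mg/dL; CDAI is the same sum
#' without the CRP term, so `sdai - cdai` equals CRP in mg/dL exactly.
#' CRP is supplied in mg/L (the package's single unit of record) and
#' converted internally.
#'
#' @inheritParams validate_visit
#' @return numeric vector of scores.
#' @examples
#' sdai(4, 4, 10, 5, 5)   # 4 + 4 + 5 + 5 + 1.0
#' cdai(4, 4, 10, 5, 5)
#' @export
sdai <- function(tjc28, sjc28, crp_mg_l, pga_cm, ega_cm) {
  validate_visit(tjc28, sjc28, crp_mg_l, pga_cm, ega_cm)
  tjc28 + sjc28 + pga_cm + ega_cm + crp_mg_l / 10
}

#' @rdname sdai
#' @export
cdai <- function(tjc28, sjc28, crp_mg_l, pga_cm, ega_cm) {
  validate_visit(tjc28, sjc28, crp_mg_l, pga_cm, ega_cm)
  tjc28 + sjc28 + pga_cm + ega_cm
}

#' EULAR response classification from paired DAS28 scores
#'
#' Classifies treatment response from the DAS28 improvement
#' (baseline minus follow-up) and the attained follow-up score, per the
#' published EULAR response matrix:
#' good requires improvement > 1.2 *and* attained score <= 3.2 (inclusive);
#' none when improvement <= 0.6, or improvement <= 1.2 with attained
#' score > 5.1; moderate otherwise. An improvement of exactly 1.2 is not
#' "good".
#'
#' @param das28_baseline,das28_followup numeric vectors of DAS28 scores
#'   (each >= 0.96), recycled to a common length.
#' @return factor with levels `good`, `moderate`, `none`.
#' @examples
#' eular_response(5.0, 3.0)  # good
#' eular_response(6.0, 5.5)  # none
#' @export
eular_response <- function(das28_baseline, das28_followup) {
  n <- max(length(das28_baseline), length(das28_followup))
  b <- rep_len(das28_baseline, n)
  f <- rep_len(das28_followup, n)
  if (any(!is.finite(b)) || any(!is.finite(f))) {
    stop("DAS28 scores must be finite", call. = FALSE)
  }
  if (any(b < 0.96) || any(f < 0.96)) {
    stop("DAS28-CRP scores below the 0.96 floor are impossible", call. = FALSE)
  }
  # improvements are compared at clinical precision: the EULAR thresholds
  # carry one decimal, so floating-point residue from score subtraction
  # must not flip a boundary cell
  delta <- round(b - f, 8)
  cat_chr <- ifelse(
    delta > 1.2 & f <= 3.2, "good",
    ifelse(delta <= 0.6 | (delta <= 1.2 & f > 5.1), "none", "moderate")
  )
  factor(cat_chr, levels = c("good", "moderate", "none"))
}

#' Compute the full disease-activity score panel for a clinical table
#'
#' Appends `das28_crp`, `sdai` and `cdai` columns to a clinical visit table
#' (see [read_clinical_csv()] for the expected columns).
#'
#' @param clinical data.frame with columns `tjc28`, `sjc28`, `crp_mg_l`,
#'   `pga_cm`, `ega_cm` (and usually `patient_id`, `visit`).
#' @return the input data.frame with three score columns appended.
#' @export
score_panel <- function(clinical) {
  need <- c("tjc28", "sjc28", "crp_mg_l", "pga_cm", "ega_cm")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  clinical$das28_crp <- das28_crp(clinical$tjc28, clinical$sjc28,
                                  clinical$crp_mg_l, clinical$pga_cm)
  clinical$sdai <- sdai(clinical$tjc28, clinical$sjc28, clinical$crp_mg_l,
                        clinical$pga_cm, clinical$ega_cm)
  clinical$cdai <- cdai(clinical$tjc28, clinical$sjc28, clinical$crp_mg_l,
                        clinical$pga_cm, clinical$ega_cm)
  clinical
}
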
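# Clinical scores, demographics, and the UHDRS-derived composites.

SCORE_NAMES <- c("tms", "tfc", "uhdrs_is", "sdmt", "vf",
                 "stroop_word", "stroop_color", "stroop_interference")

# valid ranges used for ingestion checks and prediction clipping; counts with
# no defined ceiling are open above
SCORE_RANGES <- list(
  tms = c(0, 124), tfc = c(0, 13), uhdrs_is = c(0, 100),
  sdmt = c(0, Inf), vf = c(0, Inf),
  stroop_word = c(0, Inf), stroop_color = c(0, Inf),
  stroop_interference = c(0, Inf),
  cuhdrs = c(-Inf, Inf)
)

# direction of impairment: +1 if a larger value means more impairment
SCORE_IMPAIRMENT_SIGN <- c(
  tms = 1, tfc = -1, uhdrs_is = -1, sdmt = -1, vf = -1,
  stroop_word = -1, stroop_color = -1, stroop_interference = -1, cuhdrs = -1
)

#' Composite UHDRS (cUHDRS)
#'
#' The multi-domain composite used as a single trial endpoint:
#' \deqn{cUHDRS = \frac{TFC-10.4}{1.9} - \frac{TMS-29.7}{14.9} +
#'   \frac{SDMT-28.4}{11.3} + \frac{SW-66.1}{20.1} + 10}
#' It increases with functional capacity and cognitive performance and
#' decreases with motor impairment; at the centering constants it equals 10.
#'
#' @param tfc Total Functional Capacity (0-13).
#' @param tms UHDRS Total Motor Score (0-124).
#' @param sdmt Symbol Digit Modalities Test count.
#' @param sw Stroop word count.
#' @return the composite score (vectorised).
#' @export
cuhdrs <- function(tfc, tms, sdmt, sw) {
  if (anyNA(c(tfc, tms, sdmt, sw)))
    stop("cUHDRS requires TFC, TMS, SDMT and Stroop word", call. = FALSE)
  (tfc - 10.4) / 1.9 - (tms - 29.7) / 14.9 + (sdmt - 28.4) / 11.3 +
    (sw - 66.1) / 20.1 + 10
}

#' Disease Burden Score
#'
#' Cumulative genetic-exposure proxy: \code{age * (CAG - 35.5)}.
#'
#' @param age age in years.
#' @param cag CAG repeat length on the mutant huntingtin allele (>= 36 under
#'   the inclusion criterion).
#' @return the DBS (vectorised).
#' @export
diseaseBurdenScore <- function(age, cag) age * (cag - 35.5)

#' Disease-stage classification
#'
#' Premanifest gene carriers are defined by a TFC of 13 together with a TMS
#' of at most five; everyone else is manifest.
#'
#' @param tfc,tms functional capacity and total motor score (vectorised).
#' @return character vector, `"premanifest"` or `"manifest"`.
#' @export
classifyStage <- function(tfc, tms) {
  if (anyNA(c(tfc, tms))) stop("TFC and TMS required", call. = FALSE)
  ifelse(tfc == 13 & tms <= 5, "premanifest", "manifest")
}

#' Validate a clinical-scores table
#'
#' Checks the required columns and score ranges. Out-of-range values are
#' either rejected (`strict = TRUE`) or clamped with a warning, a concession
#' to multi-centre CSVs with occasional typos.
#'
#' @param scores `data.frame` with columns `r SCORE_NAMES`.
#' @param strict reject (`TRUE`) or clamp (`FALSE`) out-of-range values.
#' @return the validated (possibly clamped) table.
#' @export
validateClinicalScores <- function(scores, strict = TRUE) {
  miss <- setdiff(SCORE_NAMES, names(scores))
  if (length(miss))
    stop("missing clinical columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (s in SCORE_NAMES) {
    rng <- SCORE_RANGES[[s]]
    bad <- which(scores[[s]] < rng[1] | scores[[s]] > rng[2])
    if (length(bad)) {
      if (strict)
        stop(sprintf("%d value(s) of %s outside [%g, %g]", length(bad), s,
                     rng[1], rng[2]), call. = FALSE)
      warning(sprintf("clamping %d out-of-range value(s) of %s", length(bad),
                      s), call. = FALSE)
      scores[[s]][bad] <- pmin(pmax(scores[[s]][bad], rng[1]), rng[2])
    }
  }
  if (any(scores$uhdrs_is %% 5 != 0))
    warning("UHDRS independence scale values not in steps of 5", call. = FALSE)
  scores
}
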
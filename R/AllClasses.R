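#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median sd var cor predict rnorm runif rbinom rlnorm quantile setNames complete.cases p.adjust wilcox.test coef plogis fft filter na.omit
#' @importFrom utils head tail read.csv write.csv adist
#' @importFrom Rcpp sourceCpp
#' @useDynLib hdspeech, .registration = TRUE
NULL

TASK_KINDS <- c("forward", "backward")

EVENT_CATEGORIES <- c(
  "number",
  "pronunciation_error_paraphasia",
  "pronunciation_error_phone_perseveration",
  "pronunciation_error_block",
  "pronunciation_error_prolongation",
  "filled_pause",
  "abnormal_breathing",
  "vocal_noise"
)

PRONUNCIATION_ERROR_CATEGORIES <- EVENT_CATEGORIES[2:5]
COLLATERAL_CATEGORIES <- c("abnormal_breathing", "vocal_noise")

.emptyEvents <- function() {
  data.frame(label = character(), category = character(),
             start = numeric(), end = numeric(), stringsAsFactors = FALSE)
}

.validateEvents <- function(ev, tier) {
  if (nrow(ev) == 0) return(NULL)
  if (any(!nzchar(ev$label))) return(sprintf("%s tier: empty labels", tier))
  if (any(!ev$category %in% EVENT_CATEGORIES))
    return(sprintf("%s tier: unknown categories: %s", tier,
                   paste(setdiff(ev$category, EVENT_CATEGORIES), collapse = ", ")))
  if (any(ev$start < 0)) return(sprintf("%s tier: negative start times", tier))
  if (any(ev$end <= ev$start))
    return(sprintf("%s tier: events must satisfy end > start", tier))
  if (is.unsorted(ev$start)) return(sprintf("%s tier: events not sorted by onset", tier))
  if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)] - 1e-9))
    return(sprintf("%s tier: overlapping events", tier))
  NULL
}

#' Time-aligned annotation of one counting task
#'
#' Holds the expert word-tier and phone-tier events of one forward or backward
#' counting recording, as produced by manual annotation plus forced alignment.
#' Events carry a label, an event category (number, one of the pooled
#' pronunciation-error categories, filled pause, abnormal breathing or vocal
#' noise) and half-open time intervals \code{[start, end)} in seconds.
#' Silences are derived, not annotated: see [deriveSilences()].
#'
#' @slot task `"forward"` or `"backward"`.
#' @slot events word-tier events (`data.frame`: label, category, start, end).
#' @slot phoneEvents phone-tier events, same columns.
#' @slot silences derived inter-event gaps (`data.frame`: start, end).
#' @slot audioRef optional path to the source audio.
#' @export
setClass("AnnotatedTask",
  representation(task = "character", events = "data.frame",
                 phoneEvents = "data.frame", silences = "data.frame",
                 audioRef = "character"),
  prototype(task = "forward", events = .emptyEvents(),
            phoneEvents = .emptyEvents(),
            silences = data.frame(start = numeric(), end = numeric()),
            audioRef = NA_character_),
  validity = function(object) {
    msg <- character()
    if (!(length(object@task) == 1L && object@task %in% TASK_KINDS))
      msg <- c(msg, "task must be 'forward' or 'backward'")
    m <- .validateEvents(object@events, "word")
    if (!is.null(m)) msg <- c(msg, m)
    m <- .validateEvents(object@phoneEvents, "phone")
    if (!is.null(m)) msg <- c(msg, m)
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AnnotatedTask
#'
#' @param task `"forward"` or `"backward"`.
#' @param events word-tier events `data.frame` with columns label, category,
#'   start, end (seconds). Rows are sorted by onset.
#' @param phoneEvents phone-tier events, same layout.
#' @param audioRef optional path to the audio file.
#' @return An [AnnotatedTask-class] object (silences not yet derived).
#' @export
AnnotatedTask <- function(task, events = .emptyEvents(),
                          phoneEvents = .emptyEvents(),
                          audioRef = NA_character_) {
  fix <- function(ev) {
    ev <- as.data.frame(ev, stringsAsFactors = FALSE)
    if (nrow(ev)) ev <- ev[order(ev$start, ev$end), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  }
  new("AnnotatedTask", task = task, events = fix(events),
      phoneEvents = fix(phoneEvents),
      silences = data.frame(start = numeric(), end = numeric()),
      audioRef = audioRef)
}

setMethod("show", "AnnotatedTask", function(object) {
  cat(sprintf("AnnotatedTask (%s counting): %d word events, %d phone events, %d silences\n",
              object@task, nrow(object@events), nrow(object@phoneEvents),
              nrow(object@silences)))
  if (nrow(object@events))
    cat(sprintf("  span %.3f - %.3f s\n", object@events$start[1],
                object@events$end[nrow(object@events)]))
})

#' Frame-level acoustic contour
#'
#' A per-frame track of fundamental frequency (Hz) or intensity (dB re full
#' scale). For F0 contours `voiced` flags frames whose periodicity confidence
#' exceeded the voicing threshold; unvoiced frames carry `NA` values.
#'
#' @slot times frame centre times in seconds, strictly increasing.
#' @slot values per-frame value (Hz or dB).
#' @slot voiced per-frame voicing flag (all `TRUE` for intensity).
#' @slot frameStep frame step in seconds.
#' @slot unit `"Hz"` or `"dB"`.
#' @export
setClass("Contour",
  representation(times = "numeric", values = "numeric", voiced = "logical",
                 frameStep = "numeric", unit = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@values) != n || length(object@voiced) != n)
      msg <- c(msg, "times, values and voiced must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@frameStep) != 1L || object@frameStep <= 0)
      msg <- c(msg, "frameStep must be a positive scalar")
    if (any(object@voiced & !is.finite(object@values)))
      msg <- c(msg, "voiced frames must carry finite values")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname Contour-class
#' @param times,values,voiced,frameStep,unit slots, see the class description.
#' @export
Contour <- function(times, values, voiced = rep(TRUE, length(times)),
                    frameStep = if (length(times) > 1) median(diff(times)) else 0.01,
                    unit = "Hz") {
  new("Contour", times = as.numeric(times), values = as.numeric(values),
      voiced = as.logical(voiced), frameStep = frameStep, unit = unit)
}

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour (%s): %d frames, step %.4g s, %.0f%% voiced\n",
              object@unit, length(object@times), object@frameStep,
              100 * mean(object@voiced)))
})

#' Per-task acoustic contours
#'
#' Bundles the F0 and intensity contours of one task plus per-word-event
#' intelligibility scores. Phonatory features consume this object, never raw
#' waveforms, so annotation-only pipelines (including the synthetic cohort
#' generator) can supply contours directly.
#'
#' @slot f0 F0 [Contour-class].
#' @slot intensity intensity [Contour-class].
#' @slot intelligibility numeric vector of per-word-event modulation-energy
#'   intelligibility scores (may be length 1 for a task-level value, or
#'   length 0 when unavailable).
#' @export
setClass("TaskContours",
  representation(f0 = "Contour", intensity = "Contour",
                 intelligibility = "numeric"))

#' @rdname TaskContours-class
#' @param f0,intensity,intelligibility slots, see the class description.
#' @export
TaskContours <- function(f0, intensity, intelligibility = numeric()) {
  new("TaskContours", f0 = f0, intensity = intensity,
      intelligibility = as.numeric(intelligibility))
}

#' Cohort container: speech features plus clinical annotation
#'
#' A `SpeechCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' one `"features"` assay: the 60 speech features (rows, keyed
#' `<task>__<feature>`) by participant visits (columns). `colData` carries the
#' demographics (sex, age, CAG repeats, disease burden score), the nine
#' clinical scores, the cUHDRS composite, the cohort label and participant /
#' visit identifiers. Ground truth from the synthetic generator, and striatal
#' volume tables, live in `metadata()`.
#'
#' @export
setClass("SpeechCohort", contains = "SummarizedExperiment")

#' Fitted ensemble predictor for one clinical score
#'
#' The result of the bounded portfolio search: the cross-validation-ranked
#' candidate pool, the greedy ensemble members and weights, the preprocessing
#' recipe (training medians for imputation, means/SDs for standardisation),
#' and training metadata (seed, number of candidates evaluated).
#'
#' @slot target clinical score name.
#' @slot inputKind one of the input-set kinds, see [fitPredictor()].
#' @slot members list of fitted member models.
#' @slot weights ensemble weights (sum to 1).
#' @slot recipe preprocessing recipe list.
#' @slot metadata list: seed, nCandidates, cvMae, clipRange, featureNames.
#' @export
setClass("TrainedPredictor",
  representation(target = "character", inputKind = "character",
                 members = "list", weights = "numeric", recipe = "list",
                 metadata = "list"),
  validity = function(object) {
    if (length(object@members) != length(object@weights))
      return("one weight per ensemble member required")
    if (length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-8)
      return("ensemble weights must sum to 1")
    TRUE
  }
)

setMethod("show", "TrainedPredictor", function(object) {
  cat(sprintf("TrainedPredictor for '%s' (%s): %d ensemble member(s), CV MAE %.3f\n",
              object@target, object@inputKind, length(object@members),
              object@metadata$cvMae))
})
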
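# The 30 per-task speech features (60 total over forward + backward counting):
# articulatory/phonatory deficiencies, rhythm and temporal statistics,
# sequence errors and perseverations, and collateral-track additions.
# Temporal rate (TR) of a segment class = total class duration / task
# duration. Missing values carry the NA sentinel.

FEATURE_NAMES <- c(
  # articulatory and phonatory deficiencies
  "pron_err_count", "pron_err_ratio", "pron_err_per_sec",
  "intelligibility_mean", "f0_sd", "f0_range",
  "intensity_norm_sd", "intensity_norm_range",
  # rhythm and temporal statistics
  "task_duration", "tr_numbers", "number_dur_mean", "numbers_per_sec",
  "number_dur_sd", "phones_per_sec", "tr_silences", "silence_dur_mean",
  "silence_dur_sd", "silence_count",
  # sequence errors and perseverations
  "number_levenshtein", "number_gestalt", "phone_levenshtein",
  "phone_gestalt", "number_count", "phone_count",
  # collateral track additions
  "abnormal_voc_count", "abnormal_voc_per_sec", "tr_abnormal_voc",
  "filled_pause_count", "filled_pause_per_sec", "tr_filled_pause"
)

#' Names of the 60 speech features
#'
#' Feature keys are `<task>__<feature>` with task `forward` or `backward`.
#'
#' @param task optionally restrict to one task.
#' @return character vector of 60 (or 30) keys.
#' @export
speechFeatureNames <- function(task = NULL) {
  if (is.null(task))
    return(c(paste0("forward__", FEATURE_NAMES),
             paste0("backward__", FEATURE_NAMES)))
  stopifnot(task %in% TASK_KINDS)
  paste0(task, "__", FEATURE_NAMES)
}

# word events that count as pronounced numbers: number-labelled events,
# including mispronounced ones (a mispronounced number is both a
# pronunciation error and a number token; sequence metrics measure ordering,
# error features articulation)
.numberEvents <- function(task, lexicon) {
  ev <- task@events
  ev[ev$label %in% lexicon$word &
       ev$category %in% c("number", PRONUNCIATION_ERROR_CATEGORIES), ,
     drop = FALSE]
}

.sdOr0 <- function(x) if (length(x) <= 1) 0 else sd(x)

#' Pronunciation-error features
#'
#' Paraphasias, phone perseverations, blocks and prolongations are pooled as
#' pronunciation errors. Returns the total count, the ratio per pronounced
#' number (0, with a warning, if no numbers were pronounced), and the rate
#' per second of task time.
#'
#' @param task an [AnnotatedTask-class] with silences derived.
#' @param lexicon a [numberLexicon()] table.
#' @return named numeric vector (count, ratio, per-second).
#' @export
pronunciationErrorFeatures <- function(task, lexicon = numberLexicon()) {
  dur <- taskDuration(task)
  if (dur <= 0) stop("zero task duration", call. = FALSE)
  nErr <- sum(task@events$category %in% PRONUNCIATION_ERROR_CATEGORIES)
  nNum <- nrow(.numberEvents(task, lexicon))
  if (nErr > 0 && nNum == 0) {
    warning("pronunciation errors present but no pronounced numbers; ",
            "error ratio set to 0", call. = FALSE)
  }
  c(pron_err_count = nErr,
    pron_err_ratio = if (nNum > 0) nErr / nNum else 0,
    pron_err_per_sec = nErr / dur)
}

#' Phonatory features from contours
#'
#' F0 statistics (SD, max-min range) over voiced frames inside word events;
#' intensity frames inside word events are normalised by subtracting their
#' mean dB (removing recording-gain differences across centres) before the SD
#' and range are taken; mean intelligibility averages the per-word-event
#' modulation-energy scores.
#'
#' @param task an [AnnotatedTask-class].
#' @param contours a [TaskContours-class].
#' @return named numeric vector of 5 features (NA where undefined).
#' @export
phonatoryFeatures <- function(task, contours) {
  ev <- task@events
  inEvents <- function(times) {
    if (nrow(ev) == 0) return(rep(FALSE, length(times)))
    out <- rep(FALSE, length(times))
    for (i in seq_len(nrow(ev)))
      out <- out | (times >= ev$start[i] & times < ev$end[i])
    out
  }
  f0 <- contours@f0
  sel <- f0@voiced & inEvents(f0@times)
  if (any(sel)) {
    v <- f0@values[sel]
    f0sd <- .sdOr0(v); f0rg <- max(v) - min(v)
  } else {
    warning("no voiced frames inside word events; F0 features missing",
            call. = FALSE)
    f0sd <- NA_real_; f0rg <- NA_real_
  }
  int <- contours@intensity
  isel <- inEvents(int@times)
  if (any(isel)) {
    w <- int@values[isel] - mean(int@values[isel])
    intsd <- .sdOr0(w); intrg <- max(w) - min(w)
  } else {
    intsd <- NA_real_; intrg <- NA_real_
  }
  intel <- contours@intelligibility
  intel <- intel[is.finite(intel)]
  c(intelligibility_mean = if (length(intel)) mean(intel) else NA_real_,
    f0_sd = f0sd, f0_range = f0rg,
    intensity_norm_sd = intsd, intensity_norm_range = intrg)
}

#' Rhythm and temporal-statistics features
#'
#' Task duration, temporal rates and per-second rates of pronounced numbers
#' and silences, mean/SD segment durations, phone rate, and the silence
#' count. The SD of a single segment is 0.
#'
#' @param task an [AnnotatedTask-class] with silences derived.
#' @param lexicon a [numberLexicon()] table.
#' @return named numeric vector of 10 features.
#' @export
rhythmFeatures <- function(task, lexicon = numberLexicon()) {
  dur <- taskDuration(task)
  if (dur <= 0) stop("zero task duration", call. = FALSE)
  num <- .numberEvents(task, lexicon)
  numDur <- num$end - num$start
  sil <- task@silences
  silDur <- sil$end - sil$start
  c(task_duration = dur,
    tr_numbers = sum(numDur) / dur,
    number_dur_mean = if (nrow(num)) mean(numDur) else 0,
    numbers_per_sec = nrow(num) / dur,
    number_dur_sd = .sdOr0(numDur),
    phones_per_sec = nrow(task@phoneEvents) / dur,
    tr_silences = sum(silDur) / dur,
    silence_dur_mean = if (nrow(sil)) mean(silDur) else 0,
    silence_dur_sd = .sdOr0(silDur),
    silence_count = nrow(sil))
}

#' Sequence-error features
#'
#' Levenshtein distance and gestalt similarity of the pronounced number
#' sequence (ordered labels of number events, mispronunciations included)
#' and of the pronounced phone sequence against the task's target, plus the
#' total numbers and phones pronounced. Phone-level metrics are NA (with a
#' warning) when the phone tier is absent.
#'
#' @param task an [AnnotatedTask-class].
#' @param target a [targetSequence()] for the same task kind.
#' @param lexicon a [numberLexicon()] table.
#' @return named numeric vector of 6 features.
#' @export
sequenceFeatures <- function(task, target = targetSequence(task@task),
                             lexicon = numberLexicon()) {
  stopifnot(target$task == task@task)
  num <- .numberEvents(task, lexicon)
  numSeq <- num$label
  out <- c(number_levenshtein = levenshteinDist(numSeq, target$numbers),
           number_gestalt = gestaltSimilarity(numSeq, target$numbers),
           phone_levenshtein = NA_real_, phone_gestalt = NA_real_,
           number_count = nrow(num),
           phone_count = nrow(task@phoneEvents))
  if (nrow(task@phoneEvents)) {
    out["phone_levenshtein"] <- levenshteinDist(task@phoneEvents$label,
                                                target$phones)
    out["phone_gestalt"] <- gestaltSimilarity(task@phoneEvents$label,
                                              target$phones)
  } else {
    warning("phone tier empty; phone-level sequence features missing",
            call. = FALSE)
    out["phone_count"] <- NA_real_
  }
  out
}

#' Collateral-track features
#'
#' Abnormal vocalizations (abnormal breathing + vocal noises) and filled
#' pauses: counts, per-second rates, and temporal rates.
#'
#' @param task an [AnnotatedTask-class] with silences derived.
#' @return named numeric vector of 6 features.
#' @export
collateralFeatures <- function(task) {
  dur <- taskDuration(task)
  if (dur <= 0) stop("zero task duration", call. = FALSE)
  ev <- task@events
  av <- ev[ev$category %in% COLLATERAL_CATEGORIES, , drop = FALSE]
  fp <- ev[ev$category == "filled_pause", , drop = FALSE]
  c(abnormal_voc_count = nrow(av),
    abnormal_voc_per_sec = nrow(av) / dur,
    tr_abnormal_voc = sum(av$end - av$start) / dur,
    filled_pause_count = nrow(fp),
    filled_pause_per_sec = nrow(fp) / dur,
    tr_filled_pause = sum(fp$end - fp$start) / dur)
}

.taskFeatures <- function(task, contours, lexicon) {
  if (nrow(task@events) == 0) {
    warning(sprintf("%s task has no word events; its 30 features are missing",
                    task@task), call. = FALSE)
    return(setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES))
  }
  phon <- if (is.null(contours)) {
    setNames(rep(NA_real_, 5),
             c("intelligibility_mean", "f0_sd", "f0_range",
               "intensity_norm_sd", "intensity_norm_range"))
  } else phonatoryFeatures(task, contours)
  out <- c(pronunciationErrorFeatures(task, lexicon),
           phon,
           rhythmFeatures(task, lexicon),
           sequenceFeatures(task, targetSequence(task@task, lexicon), lexicon),
           collateralFeatures(task))
  out[FEATURE_NAMES]
}

#' Extract the full 60-feature vector for one visit
#'
#' Computes the 30 per-task features for the forward and backward counting
#' tasks and returns them keyed `<task>__<feature>`. Either task may be
#' empty-annotated, in which case its 30 features carry the NA sentinel.
#' The extraction is a pure function of its inputs.
#'
#' @param forward,backward [AnnotatedTask-class] objects (silences derived).
#' @param forwardContours,backwardContours optional [TaskContours-class];
#'   when absent the phonatory features are NA.
#' @param lexicon a [numberLexicon()] table.
#' @return named numeric vector with exactly 60 entries.
#' @export
extractFeatures <- function(forward, backward,
                            forwardContours = NULL, backwardContours = NULL,
                            lexicon = numberLexicon()) {
  stopifnot(forward@task == "forward", backward@task == "backward")
  f <- .taskFeatures(forward, forwardContours, lexicon)
  b <- .taskFeatures(backward, backwardContours, lexicon)
  setNames(c(f, b), speechFeatureNames())
}
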
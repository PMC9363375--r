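# Synthetic-cohort generator. A single latent disease-severity scalar
# (standardised disease burden plus noise) drives demographics-linked
# clinical scores, annotation timelines for both counting tasks, acoustic
# contours and striatal volumes, so that every pipeline stage can be
# exercised end to end and ordering claims (speech beats demographics,
# backward beats forward) are well-posed, testable generator properties.
# Calibration targets are first/second moments of the study cohort: age
# 50.7 (11.2), CAG 44.0 (3.6), 36 exploration + 67 validation participants,
# forward/backward task durations 10.7 (3.6) / 15.6 (5.6) s, and the
# clinical-score means/SDs of the cohort table.

.defaultScoreLinks <- function() {
  data.frame(
    score = SCORE_NAMES,
    mean = c(29.6, 10.8, 87.8, 29.4, 27.8, 67.6, 50.3, 28.8),
    sd   = c(18.6,  2.0, 11.8, 13.4, 11.8, 22.1, 16.7, 11.6),
    # signed severity loading: TMS increases with severity, all others
    # decrease; magnitudes are typical cross-domain disease correlations
    r    = c(0.75, -0.75, -0.70, -0.75, -0.60, -0.70, -0.70, -0.65),
    min  = c(0, 0, 0, 0, 0, 0, 0, 0),
    max  = c(124, 13, 100, 110, 100, 130, 130, 110),
    step = c(1, 1, 5, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

.defaultTaskParams <- function() {
  # gap location solves E[duration] = 20 mu_num + 19 E[gap] = target with
  # E[gap] = exp(mu0 + sdlog^2/2 + slope^2/2) under severity ~ N(0,1)
  list(
    forward = list(
      numberDurMean = 0.35, numberDurSD = 0.07, numberDurSlope = 0.04,
      gapMeanTarget = (10.7 - 20 * 0.35) / 19, gapSdLog = 0.50,
      gapSevSlope = 0.55, logitSlope = 1.3,
      errIntercept = -3.5, omitIntercept = -3.5, persevIntercept = -3.5,
      fillerIntercept = -3.0, abnormalIntercept = -3.3),
    backward = list(
      numberDurMean = 0.45, numberDurSD = 0.09, numberDurSlope = 0.05,
      gapMeanTarget = (15.6 - 20 * 0.45) / 19, gapSdLog = 0.55,
      gapSevSlope = 0.65, logitSlope = 1.3 * 1.25,
      errIntercept = -3.5, omitIntercept = -3.5, persevIntercept = -3.5,
      fillerIntercept = -3.0, abnormalIntercept = -3.3))
}

#' Synthetic-cohort generator configuration
#'
#' Defaults encode the study conditions: 103 participants (36 exploration /
#' 67 validation), age 50.7 (11.2) years in [27, 88], CAG 44.0 (3.6) with a
#' pathogenic floor of 36, roughly one visit in five repeated, and task
#' durations calibrated to 10.7 s (forward) and 15.6 s (backward). Backward
#' severity slopes exceed forward ones by construction — the generator
#' encodes the greater cognitive load of backward counting as a testable
#' assumption.
#'
#' @param nParticipants cohort size.
#' @param explorationFraction fraction assigned to the exploration cohort.
#' @param secondVisitFraction fraction of participants with a second visit.
#' @param femaleFraction fraction of female participants.
#' @param ageMean,ageSD,ageRange truncated-normal age model (years).
#' @param cagMean,cagSD,cagMin,cagMax truncated-normal CAG repeats (integer).
#' @param severityNoiseSD SD of the latent-severity noise added to the
#'   standardised disease burden score (severity is then restandardised).
#' @param progressionPerVisit severity increment at a second visit.
#' @param scoreLinks per-score linear severity links (mean, sd, signed r,
#'   valid range, rounding step).
#' @param taskParams per-task timeline parameters (see source).
#' @param f0Base named vector, base F0 by sex (Hz).
#' @param volumeBaselinePct,volumeSlopePct,volumeNoisePct striatal volume
#'   percentage model: baseline - slope x severity + noise.
#' @param nVolumes validation participants receiving an MRI volume row.
#' @return configuration list.
#' @export
generatorConfig <- function(nParticipants = 103,
                            explorationFraction = 36 / 103,
                            secondVisitFraction = 23 / 103,
                            femaleFraction = 63 / 103,
                            ageMean = 50.7, ageSD = 11.2,
                            ageRange = c(27, 88),
                            cagMean = 44.0, cagSD = 3.6,
                            cagMin = 36, cagMax = 60,
                            severityNoiseSD = 0.8,
                            progressionPerVisit = 0.15,
                            scoreLinks = .defaultScoreLinks(),
                            taskParams = .defaultTaskParams(),
                            f0Base = c(F = 200, M = 120),
                            volumeBaselinePct = 1.3,
                            volumeSlopePct = 0.12,
                            volumeNoisePct = 0.12,
                            nVolumes = 36) {
  stopifnot(ageSD > 0, cagSD > 0, severityNoiseSD > 0,
            ageRange[1] < ageRange[2], cagMin >= 36)
  as.list(environment())
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate one annotated counting task
#'
#' Emits the 20 target numbers in order; each is independently omitted or
#' followed by a perseverative repeat with severity-dependent logistic
#' probabilities, flagged as a pronunciation error with the same mechanism,
#' and separated by log-normal silent gaps whose location increases with
#' severity (backward slope > forward). Filled pauses and abnormal
#' vocalizations are placed inside sufficiently long gaps (never altering
#' total task time). The phone tier lays the lexicon phones of each number
#' across its span, perturbed when the number is mispronounced.
#'
#' @param severity latent severity (standardised scale).
#' @param task `"forward"` or `"backward"`.
#' @param cfg a [generatorConfig()].
#' @param lexicon a [numberLexicon()] (default abstract digits lexicon).
#' @return an [AnnotatedTask-class] with silences derived.
#' @export
generateAnnotation <- function(severity, task = c("forward", "backward"),
                               cfg = generatorConfig(),
                               lexicon = numberLexicon("digits")) {
  task <- match.arg(task)
  p <- cfg$taskParams[[task]]
  stopifnot(is.finite(severity))
  pErr <- plogis(p$errIntercept + p$logitSlope * severity)
  pOmit <- plogis(p$omitIntercept + p$logitSlope * severity)
  pPersev <- plogis(p$persevIntercept + p$logitSlope * severity)
  pFill <- plogis(p$fillerIntercept + p$logitSlope * severity)
  pAbn <- plogis(p$abnormalIntercept + p$logitSlope * severity)

  ord <- if (task == "forward") 1:20 else 20:1
  tokens <- integer(0)
  for (n in ord) {
    if (rbinom(1, 1, pOmit) == 0) tokens <- c(tokens, n)
    if (rbinom(1, 1, pPersev) == 1) tokens <- c(tokens, n)
  }
  if (!length(tokens)) tokens <- ord[1]

  mu0 <- log(p$gapMeanTarget) - p$gapSdLog^2 / 2 - p$gapSevSlope^2 / 2
  words <- list()
  phones <- list()
  t <- 0
  for (i in seq_along(tokens)) {
    n <- tokens[i]
    dur <- max(0.08, rnorm(1, p$numberDurMean + p$numberDurSlope * severity,
                           p$numberDurSD))
    isErr <- rbinom(1, 1, pErr) == 1
    cat_ <- if (isErr) sample(PRONUNCIATION_ERROR_CATEGORIES, 1) else "number"
    words[[length(words) + 1L]] <- data.frame(
      label = lexicon$word[match(n, lexicon$number)], category = cat_,
      start = t, end = t + dur, stringsAsFactors = FALSE)
    ph <- strsplit(lexicon$phones[match(n, lexicon$number)], " ",
                   fixed = TRUE)[[1]]
    if (isErr) {
      if (length(ph) > 1 && runif(1) < 0.5) ph <- ph[-sample(length(ph), 1)]
      else ph <- append(ph, ph[sample(length(ph), 1)], after = length(ph))
    }
    edges <- seq(t, t + dur, length.out = length(ph) + 1)
    phones[[length(phones) + 1L]] <- data.frame(
      label = ph, category = "number",
      start = edges[-length(edges)], end = edges[-1],
      stringsAsFactors = FALSE)
    t <- t + dur
    if (i < length(tokens)) {
      gap <- rlnorm(1, mu0 + p$gapSevSlope * severity, p$gapSdLog)
      coll <- NULL
      if (rbinom(1, 1, pFill) == 1) {
        coll <- data.frame(label = "euh", category = "filled_pause",
                           stringsAsFactors = FALSE)
      } else if (rbinom(1, 1, pAbn) == 1) {
        coll <- data.frame(
          label = sample(c("[breath]", "[noise]"), 1),
          category = sample(COLLATERAL_CATEGORIES, 1),
          stringsAsFactors = FALSE)
      }
      if (!is.null(coll)) {
        cdur <- min(rlnorm(1, log(0.3), 0.4), gap * 0.6)
        if (gap > cdur + 0.08) {
          off <- runif(1, 0.02, gap - cdur - 0.02)
          coll$start <- t + off
          coll$end <- t + off + cdur
          words[[length(words) + 1L]] <- coll
        }
      }
      t <- t + gap
    }
  }
  at <- AnnotatedTask(task, do.call(rbind, words), do.call(rbind, phones))
  deriveSilences(at)
}

#' Generate acoustic contours for a synthetic task
#'
#' F0 is voiced only inside word events, centred on the sex-specific base
#' (200 Hz female / 120 Hz male) with per-frame variability increasing in
#' severity; intensity carries per-event level jitter whose spread also
#' grows with severity; intelligibility decreases linearly in severity.
#'
#' @param task an [AnnotatedTask-class].
#' @param sex `"F"` or `"M"`.
#' @param severity latent severity.
#' @param cfg a [generatorConfig()].
#' @return a [TaskContours-class].
#' @export
generateContours <- function(task, sex, severity, cfg = generatorConfig()) {
  ev <- task@events
  tmax <- if (nrow(ev)) max(ev$end) else 1
  times <- seq(0.005, tmax, by = 0.01)
  inEv <- rep(FALSE, length(times))
  for (i in seq_len(nrow(ev)))
    inEv <- inEv | (times >= ev$start[i] & times < ev$end[i])
  base <- unname(cfg$f0Base[sex])
  f0sd <- max(0.5, 4 + 2.5 * severity)
  f0v <- rep(NA_real_, length(times))
  f0v[inEv] <- pmin(400, pmax(60,
    base + rnorm(sum(inEv), 0, f0sd) +
      f0sd * sin(2 * pi * 0.7 * times[inEv])))
  f0 <- Contour(times, f0v, voiced = inEv, frameStep = 0.01, unit = "Hz")

  lvlSd <- max(0.3, 1.5 + 0.8 * severity)
  intv <- rep(-60, length(times))
  for (i in seq_len(nrow(ev))) {
    sel <- times >= ev$start[i] & times < ev$end[i]
    intv[sel] <- -25 + rnorm(1, 0, lvlSd) + rnorm(sum(sel), 0, 0.8)
  }
  int <- Contour(times, intv, voiced = rep(TRUE, length(times)),
                 frameStep = 0.01, unit = "dB")
  nEv <- max(1L, nrow(ev))
  intel <- pmax(0.05, 3 - 0.5 * severity + rnorm(nEv, 0, 0.3))
  TaskContours(f0, int, intel)
}

#' Generate a striatal-volume table
#'
#' Striatal volume percentage = baseline - slope x severity + noise
#' (truncated positive); the estimated intracranial volume is drawn
#' independently (with a sex offset) and the total striatal volume is split
#' into caudate, putamen and ventral striatum.
#'
#' @param severities latent severities.
#' @param sexes `"F"`/`"M"` per participant.
#' @param cfg a [generatorConfig()].
#' @return `data.frame`: caudate, putamen, ventral_striatum, etiv (mL).
#' @export
generateStriatalVolumes <- function(severities, sexes,
                                    cfg = generatorConfig()) {
  stopifnot(all(is.finite(severities)), length(sexes) == length(severities))
  n <- length(severities)
  pct <- pmax(0.25, cfg$volumeBaselinePct - cfg$volumeSlopePct * severities +
                rnorm(n, 0, cfg$volumeNoisePct))
  etiv <- .rtruncnorm(n, 1450 + 100 * (sexes == "M"), 100, 1000, 2000)
  tot <- pct / 100 * etiv
  w <- cbind(rnorm(n, 0.40, 0.02), rnorm(n, 0.52, 0.02), rnorm(n, 0.08, 0.01))
  w <- pmax(w, 0.02) / rowSums(pmax(w, 0.02))
  data.frame(caudate = tot * w[, 1], putamen = tot * w[, 2],
             ventral_striatum = tot * w[, 3], etiv = etiv)
}

#' Generate a full synthetic cohort
#'
#' Draws demographics, computes the disease burden score, forms the latent
#' severity (standardised DBS plus noise, restandardised), links the nine
#' clinical scores to it, assigns cohort labels and second visits, and
#' generates per-visit annotation timelines, contours and (for a subset of
#' validation participants) striatal volumes. Fully deterministic per seed.
#'
#' @param cfg a [generatorConfig()].
#' @param seed integer seed.
#' @return list of class `SyntheticCohort`: `participants`, `visits`,
#'   `tasks`, `contours`, `volumes`, `groundTruth`.
#' @export
generateCohort <- function(cfg = generatorConfig(), seed = 1) {
  set.seed(seed)
  n <- cfg$nParticipants
  nExpl <- round(cfg$explorationFraction * n)
  ids <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(runif(n) < cfg$femaleFraction, "F", "M")
  age <- .rtruncnorm(n, cfg$ageMean, cfg$ageSD, cfg$ageRange[1],
                     cfg$ageRange[2])
  cag <- round(.rtruncnorm(n, cfg$cagMean, cfg$cagSD, cfg$cagMin - 0.49,
                           cfg$cagMax + 0.49))
  cag <- pmin(pmax(cag, cfg$cagMin), cfg$cagMax)
  dbs <- diseaseBurdenScore(age, cag)
  z <- as.numeric(scale(dbs))
  sev <- (z + rnorm(n, 0, cfg$severityNoiseSD)) /
    sqrt(1 + cfg$severityNoiseSD^2)
  second <- runif(n) < cfg$secondVisitFraction
  cohort <- rep(c("exploration", "validation"), c(nExpl, n - nExpl))

  participants <- data.frame(participant_id = ids, cohort = cohort,
                             sex = sex, stringsAsFactors = FALSE)

  drawScores <- function(sv) {
    L <- cfg$scoreLinks
    vals <- lapply(seq_len(nrow(L)), function(i) {
      v <- L$mean[i] + L$r[i] * L$sd[i] * sv +
        sqrt(1 - L$r[i]^2) * L$sd[i] * rnorm(length(sv))
      v <- pmin(pmax(v, L$min[i]), L$max[i])
      round(v / L$step[i]) * L$step[i]
    })
    setNames(as.data.frame(vals), L$score)
  }

  visitRows <- list()
  tasks <- list()
  contours <- list()
  truthSlope <- lapply(cfg$taskParams, `[[`, "gapSevSlope")
  for (i in seq_len(n)) {
    nv <- if (second[i]) 2L else 1L
    for (v in seq_len(nv)) {
      sv <- sev[i] + (v - 1L) * cfg$progressionPerVisit
      ageV <- age[i] + (v - 1L) * runif(1, 1, 3)
      vid <- sprintf("%s_v%d", ids[i], v)
      sc <- drawScores(sv)
      visitRows[[length(visitRows) + 1L]] <- cbind(
        data.frame(visit_id = vid, participant_id = ids[i], visit_index = v,
                   cohort = cohort[i], sex = sex[i], age = ageV, cag = cag[i],
                   dbs = diseaseBurdenScore(ageV, cag[i]),
                   severity = sv, stringsAsFactors = FALSE), sc)
      fw <- generateAnnotation(sv, "forward", cfg)
      bw <- generateAnnotation(sv, "backward", cfg)
      tasks[[vid]] <- list(forward = fw, backward = bw)
      contours[[vid]] <- list(
        forward = generateContours(fw, sex[i], sv, cfg),
        backward = generateContours(bw, sex[i], sv, cfg))
    }
  }
  visits <- do.call(rbind, visitRows)
  visits$cuhdrs <- cuhdrs(visits$tfc, visits$tms, visits$sdmt,
                          visits$stroop_word)
  visits$stage <- classifyStage(visits$tfc, visits$tms)

  volIdx <- which(cohort == "validation")[seq_len(min(cfg$nVolumes,
                                                      n - nExpl))]
  volumes <- cbind(data.frame(participant_id = ids[volIdx],
                              stringsAsFactors = FALSE),
                   generateStriatalVolumes(sev[volIdx], sex[volIdx], cfg))
  volumes$striatal_pct <- striatalVolumePercent(
    volumes$caudate, volumes$putamen, volumes$ventral_striatum, volumes$etiv)

  structure(list(
    participants = participants, visits = visits, tasks = tasks,
    contours = contours, volumes = volumes,
    groundTruth = list(severity = setNames(sev, ids),
                       gapSevSlope = truthSlope,
                       scoreLinks = cfg$scoreLinks, seed = seed)),
    class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d participants (%d exploration), %d visits, %d volume rows\n",
              nrow(x$participants),
              sum(x$participants$cohort == "exploration"),
              nrow(x$visits), nrow(x$volumes)))
  invisible(x)
}

#' Assemble a SpeechCohort container
#'
#' @param features 60 x visits feature matrix (rows = [speechFeatureNames()]).
#' @param colData per-visit annotation `data.frame` (demographics, scores).
#' @param metadata list stored in the container metadata.
#' @return a [SpeechCohort-class].
#' @export
SpeechCohort <- function(features, colData, metadata = list()) {
  stopifnot(identical(rownames(features), speechFeatureNames()))
  if (!is.null(colnames(features))) rownames(colData) <- colnames(features)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features),
    colData = S4Vectors::DataFrame(colData), metadata = metadata)
  new("SpeechCohort", se)
}

#' Speech feature matrix of a cohort
#'
#' Accessor for the `"features"` assay (60 features x visits).
#'
#' @param x a [SpeechCohort-class].
#' @return numeric matrix.
#' @export
speechFeatures <- function(x) SummarizedExperiment::assay(x, "features")

#' Feature table in long layout
#'
#' One row per visit: participant/visit identifiers followed by the 60
#' feature columns — the layout written by the command-line `extract` step.
#'
#' @param x a [SpeechCohort-class].
#' @return `data.frame`.
#' @export
featureTable <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(cd[, intersect(c("participant_id", "visit_index"), names(cd)),
           drop = FALSE],
        as.data.frame(t(speechFeatures(x))))
}

#' Generate a cohort and extract its features
#'
#' Runs [generateCohort()] and the 60-feature extraction over every visit,
#' returning the assembled [SpeechCohort-class] (ground truth and volumes in
#' `metadata()`).
#'
#' @param cfg a [generatorConfig()].
#' @param seed integer seed.
#' @return a [SpeechCohort-class].
#' @export
buildCohort <- function(cfg = generatorConfig(), seed = 1) {
  syn <- generateCohort(cfg, seed)
  lex <- numberLexicon("digits")
  featList <- lapply(syn$visits$visit_id, function(vid) {
    extractFeatures(syn$tasks[[vid]]$forward, syn$tasks[[vid]]$backward,
                    syn$contours[[vid]]$forward, syn$contours[[vid]]$backward,
                    lexicon = lex)
  })
  features <- do.call(cbind, featList)
  colnames(features) <- syn$visits$visit_id
  SpeechCohort(features, syn$visits,
               metadata = list(groundTruth = syn$groundTruth,
                               volumes = syn$volumes))
}

#' Write a synthetic cohort to disk
#'
#' TextGrids (one per visit and task), contour CSVs, demographics/clinical
#' CSVs, the volume table and the ground truth JSON. Output is byte-identical
#' across runs for the same seed.
#'
#' @param syn a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(syn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "textgrids"), showWarnings = FALSE)
  dir.create(file.path(dir, "contours"), showWarnings = FALSE)
  for (vid in names(syn$tasks)) {
    for (tk in TASK_KINDS) {
      writeTextGrid(syn$tasks[[vid]][[tk]],
                    file.path(dir, "textgrids",
                              sprintf("%s_%s.TextGrid", vid, tk)))
      co <- syn$contours[[vid]][[tk]]
      df <- data.frame(time = co@f0@times,
                       f0 = round(co@f0@values, 4),
                       voiced = co@f0@voiced,
                       intensity = round(co@intensity@values, 4))
      write.csv(df, file.path(dir, "contours",
                              sprintf("%s_%s.csv", vid, tk)),
                row.names = FALSE)
    }
  }
  write.csv(syn$visits, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(syn$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write.csv(syn$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(severity = as.list(syn$groundTruth$severity),
         gapSevSlope = syn$groundTruth$gapSevSlope,
         seed = syn$groundTruth$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
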
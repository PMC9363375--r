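test_that("cohort structure matches the configured study design", {
  syn <- generateCohort(seed = 2)
  expect_equal(nrow(syn$participants), 103)
  expect_equal(sum(syn$participants$cohort == "exploration"), 36)
  expect_equal(sum(syn$participants$cohort == "validation"), 67)
  expect_equal(nrow(syn$volumes), 36)
  expect_true(all(syn$visits$cag >= 36))
  expect_true(all(syn$visits$age > 0))
  expect_equal(syn$visits$dbs,
               diseaseBurdenScore(syn$visits$age, syn$visits$cag))
  # every visit has both tasks and contours
  expect_setequal(names(syn$tasks), syn$visits$visit_id)
  expect_setequal(names(syn$contours), syn$visits$visit_id)
})

test_that("demographic calibration holds over repeated seeds", {
  ages <- vapply(0:19, function(s) {
    syn <- generateCohort(generatorConfig(nParticipants = 103), seed = s)
    mean(syn$visits$age[syn$visits$visit_index == 1])
  }, numeric(1))
  expect_lt(abs(mean(ages) - 50.7), 1.5)
  cags <- vapply(0:4, function(s)
    mean(generateCohort(seed = s)$participants$cohort == "exploration"),
    numeric(1))
  expect_true(all(cags == 36 / 103))
})

test_that("null score links decouple scores from disease burden", {
  cfg <- generatorConfig(nParticipants = 400, secondVisitFraction = 0)
  cfg$scoreLinks$r <- rep(0, nrow(cfg$scoreLinks))
  syn <- generateCohort(cfg, seed = 6)
  for (s in c("tms", "sdmt", "tfc"))
    expect_lt(abs(cor(syn$visits[[s]], syn$visits$dbs)), 0.1)
})

test_that("low severity produces clean recitations", {
  set.seed(1)
  clean <- replicate(1000, {
    task <- generateAnnotation(-3, "forward")
    noErr <- !any(task@events$category %in%
                    hdspeech:::PRONUNCIATION_ERROR_CATEGORIES)
    lev <- levenshteinDist(
      task@events$label[task@events$label %in% as.character(1:20)],
      as.character(1:20))
    noErr && lev == 0
  })
  expect_gte(mean(clean), 0.95)
})

test_that("silence durations increase monotonically with severity", {
  set.seed(2)
  meanSil <- vapply(c(-2, 0, 2), function(sv) {
    mean(vapply(1:400, function(i) {
      task <- generateAnnotation(sv, "backward")
      sil <- task@silences
      if (nrow(sil)) mean(sil$end - sil$start) else 0
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanSil) > 0))
})

test_that("contours encode sex, voicing and severity as designed", {
  set.seed(3)
  task <- generateAnnotation(0, "forward")
  coM <- generateContours(task, "M", 0)
  medM <- median(coM@f0@values[coM@f0@voiced])
  expect_lt(abs(medM - 120), 5)
  coF <- generateContours(task, "F", 0)
  expect_lt(abs(median(coF@f0@values[coF@f0@voiced]) - 200), 5)

  # voiced frames only inside word events
  ev <- task@events
  inside <- rep(FALSE, length(coM@f0@times))
  for (i in seq_len(nrow(ev)))
    inside <- inside | (coM@f0@times >= ev$start[i] &
                          coM@f0@times < ev$end[i])
  expect_true(all(!coM@f0@voiced[!inside]))

  # no word events: empty voiced set
  expect_equal(sum(generateContours(AnnotatedTask("forward"), "M",
                                    0)@f0@voiced), 0)

  # F0 variability grows with severity (expectation over draws)
  sds <- vapply(c(-2, 0, 2), function(sv) {
    mean(vapply(1:30, function(i) {
      t2 <- generateAnnotation(sv, "forward")
      c2 <- generateContours(t2, "M", sv)
      sd(c2@f0@values[c2@f0@voiced])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("striatal volumes track severity with the configured slope", {
  set.seed(4)
  sev <- rnorm(500)
  sexes <- sample(c("F", "M"), 500, replace = TRUE)
  vols <- generateStriatalVolumes(sev, sexes)
  expect_true(all(vols$caudate > 0 & vols$putamen > 0 &
                    vols$ventral_striatum > 0))
  pct <- striatalVolumePercent(vols$caudate, vols$putamen,
                               vols$ventral_striatum, vols$etiv)
  expect_lte(cor(pct, sev, method = "spearman")[1], -0.4)

  # null slope decouples volume from severity
  cfg0 <- generatorConfig(volumeSlopePct = 0)
  vols0 <- generateStriatalVolumes(sev, sexes, cfg0)
  pct0 <- striatalVolumePercent(vols0$caudate, vols0$putamen,
                                vols0$ventral_striatum, vols0$etiv)
  expect_lt(abs(cor(pct0, sev, method = "spearman")), 0.1)

  # at the screened sample size the association is still strong
  expect_lte(cor(pct[1:36], sev[1:36], method = "spearman"), -0.4)
})

test_that("written cohorts are byte-identical across runs of one seed", {
  cfg <- generatorConfig(nParticipants = 6, nVolumes = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(generateCohort(cfg, seed = 11), d1)
  writeCohort(generateCohort(cfg, seed = 11), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  # and generated TextGrids re-ingest cleanly
  tg <- list.files(file.path(d1, "textgrids"), full.names = TRUE)[1]
  task <- readTextGrid(tg, "backward", lexicon = numberLexicon("digits"))
  expect_gt(nrow(task@events), 0)
})

test_that("extraction recovers the silence severity slope", {
  cfg <- generatorConfig()
  # collateral insertions split silences; disable them to isolate the
  # gap-location mechanism whose slope is being recovered
  cfg$taskParams$backward$fillerIntercept <- -Inf
  cfg$taskParams$backward$abnormalIntercept <- -Inf
  set.seed(5)
  sev <- rnorm(500)
  logSil <- vapply(sev, function(sv) {
    task <- generateAnnotation(sv, "backward", cfg)
    task <- deriveSilences(task, minSilence = 0.01)
    log(mean(task@silences$end - task@silences$start))
  }, numeric(1))
  slope <- coef(lm(logSil ~ sev))[2]
  truth <- cfg$taskParams$backward$gapSevSlope
  expect_lt(abs(slope - truth) / truth, 0.15)
})

test_that("generated cohorts pass ingestion validation without warnings", {
  syn <- generateCohort(generatorConfig(nParticipants = 20), seed = 8)
  expect_silent(validateClinicalScores(
    syn$visits[, hdspeech:::SCORE_NAMES]))
  for (vid in head(syn$visits$visit_id, 5)) {
    expect_true(validObject(syn$tasks[[vid]]$forward))
    expect_true(validObject(syn$tasks[[vid]]$backward))
  }
})
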
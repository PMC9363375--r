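lexD <- numberLexicon("digits")

test_that("pronunciation-error features pool the four error categories", {
  task <- makeTask("forward",
                   labels = as.character(c(1:20, 21, 22))[1:20],
                   categories = c(rep("number", 18),
                                  "pronunciation_error_paraphasia",
                                  "pronunciation_error_block"),
                   starts = (0:19) * 0.5, ends = (0:19) * 0.5 + 0.4)
  # duration = 19*0.5 + 0.4 = 9.9; force a round 10 s span
  task@events$end[20] <- 10
  out <- pronunciationErrorFeatures(task, lexD)
  expect_equal(unname(out), c(2, 2 / 20, 2 / 10))

  clean <- makeCleanTask(n = 5)
  expect_equal(unname(pronunciationErrorFeatures(clean, lexD)), c(0, 0, 0))

  # errors but no pronounced numbers: ratio 0 with a warning
  odd <- makeTask("forward", labels = "noise",
                  categories = "pronunciation_error_block",
                  starts = 0, ends = 1)
  expect_warning(out2 <- pronunciationErrorFeatures(odd, lexD), "ratio")
  expect_equal(unname(out2["pron_err_ratio"]), 0)
})

test_that("phonatory features reduce contours inside word events", {
  task <- makeTask("forward", labels = c("1", "2"),
                   categories = rep("number", 2),
                   starts = c(0, 1), ends = c(0.5, 1.5))
  times <- seq(0.005, 1.5, by = 0.01)
  inside <- (times < 0.5) | (times >= 1 & times < 1.5)

  # constant F0 and intensity: all spreads zero
  f0 <- Contour(times, ifelse(inside, 150, NA), voiced = inside)
  int <- Contour(times, rep(-30, length(times)), unit = "dB")
  out <- phonatoryFeatures(task, TaskContours(f0, int, 2.5))
  expect_equal(unname(out[c("f0_sd", "f0_range")]), c(0, 0))
  expect_equal(unname(out[c("intensity_norm_sd", "intensity_norm_range")]),
               c(0, 0))
  expect_equal(unname(out["intelligibility_mean"]), 2.5)

  # two-level F0, half the voiced frames at 100 Hz and half at 200 Hz
  n1 <- sum(times < 0.5); n2 <- sum(times >= 1 & times < 1.5)
  expect_equal(n1, n2)
  f0v <- rep(NA_real_, length(times))
  f0v[times < 0.5] <- 100
  f0v[times >= 1 & times < 1.5] <- 200
  out2 <- phonatoryFeatures(task, TaskContours(
    Contour(times, f0v, voiced = inside), int, numeric(0)))
  expect_equal(unname(out2["f0_range"]), 100)
  expect_equal(unname(out2["f0_sd"]), sd(rep(c(100, 200), each = n1)))

  # no voiced frames: F0 features carry the missing sentinel
  expect_warning(
    out3 <- phonatoryFeatures(task, TaskContours(
      Contour(times, rep(NA_real_, length(times)),
              voiced = rep(FALSE, length(times))), int, numeric(0))),
    "voiced")
  expect_true(all(is.na(out3[c("f0_sd", "f0_range")])))
})

test_that("rhythm features match a fully hand-computed fixture", {
  # numbers at [0,0.5], [1.0,1.5], [2.0,2.5]: duration 2.5, two 0.5 s gaps
  task <- makeTask("forward", labels = c("1", "2", "3"),
                   categories = rep("number", 3),
                   starts = c(0, 1, 2), ends = c(0.5, 1.5, 2.5),
                   phoneLabels = c("P01", "P02", "P03", "P04"),
                   phoneStarts = c(0, 0.25, 1.0, 2.0),
                   phoneEnds = c(0.25, 0.5, 1.5, 2.5))
  out <- rhythmFeatures(task, lexD)
  expect_equal(unname(out), c(
    2.5,            # task duration
    1.5 / 2.5,      # TR numbers
    0.5,            # mean number duration
    3 / 2.5,        # numbers per second
    0,              # SD number duration
    4 / 2.5,        # phones per second
    1.0 / 2.5,      # TR silences = 0.4
    0.5,            # mean silence duration
    0,              # SD silence duration
    2))             # silence count

  # one number of 1 s in a 2 s task
  t2 <- makeTask("forward", labels = c("1", "2"),
                 categories = rep("number", 2),
                 starts = c(0, 1.8), ends = c(1, 2))
  expect_equal(unname(rhythmFeatures(t2, lexD)["tr_numbers"]), 1.2 / 2)

  # no silences: rates and spreads are zero
  t3 <- makeTask("forward", labels = c("1", "2"),
                 categories = rep("number", 2),
                 starts = c(0, 0.5), ends = c(0.5, 1.0))
  expect_equal(unname(rhythmFeatures(t3, lexD)[c(
    "tr_silences", "silence_dur_mean", "silence_dur_sd", "silence_count")]),
    c(0, 0, 0, 0))
})

test_that("sequence features compare against the task target", {
  clean <- makeCleanTask("forward", n = 20)
  out <- sequenceFeatures(clean, lexicon = lexD)
  expect_equal(unname(out["number_levenshtein"]), 0)
  expect_equal(unname(out["number_gestalt"]), 1)
  expect_equal(unname(out["phone_levenshtein"]), 0)
  expect_equal(unname(out["number_count"]), 20)
  expect_equal(unname(out["phone_count"]), 40)

  # stopping at 15: five deletions
  part <- makeCleanTask("forward", n = 15)
  expect_equal(unname(sequenceFeatures(part,
                                       target = targetSequence("forward", lexD),
                                       lexicon = lexD)["number_levenshtein"]),
               5)

  # injected edits match the metrics computed by the oracles
  set.seed(21)
  for (i in 1:10) {
    tokens <- as.character(1:20)
    drop <- sample(20, sample(0:3, 1))
    if (length(drop)) tokens <- tokens[-drop]
    ins <- sample(length(tokens), 1)
    tokens <- append(tokens, tokens[ins], after = ins)  # one perseveration
    n <- length(tokens)
    starts <- (seq_len(n) - 1) * 0.6
    task <- makeTask("forward", labels = tokens,
                     categories = rep("number", n),
                     starts = starts, ends = starts + 0.4)
    expect_warning(out <- sequenceFeatures(task, lexicon = lexD),
                   "phone tier")
    expect_equal(unname(out["number_levenshtein"]),
                 levOracle(tokens, as.character(1:20)))
    expect_equal(unname(out["number_gestalt"]),
                 gestaltOracle(tokens, as.character(1:20)))
  }

  # backward target is the reverse recitation
  bw <- targetSequence("backward", lexD)
  expect_equal(bw$numbers, as.character(20:1))
  expect_equal(bw$phones[1:2], c("P39", "P40"))
})

test_that("collateral features count abnormal vocalizations and filled pauses", {
  none <- makeCleanTask(n = 5)
  expect_equal(unname(collateralFeatures(none)), rep(0, 6))

  # one 0.5 s filled pause in a 10 s task
  t1 <- makeTask("forward", labels = c("1", "euh", "2"),
                 categories = c("number", "filled_pause", "number"),
                 starts = c(0, 4, 9.6), ends = c(0.4, 4.5, 10))
  out <- collateralFeatures(t1)
  expect_equal(unname(out[c("filled_pause_count", "filled_pause_per_sec",
                            "tr_filled_pause")]), c(1, 0.1, 0.05))

  # mixed fixture: 2 breaths + 1 noise + 3 filled pauses
  labs <- c("1", "[breath]", "euh", "2", "[noise]", "euh", "3", "[breath]",
            "euh", "4")
  cats <- c("number", "abnormal_breathing", "filled_pause", "number",
            "vocal_noise", "filled_pause", "number", "abnormal_breathing",
            "filled_pause", "number")
  starts <- (0:9) * 1
  t2 <- makeTask("forward", labels = labs, categories = cats,
                 starts = starts, ends = starts + 0.5)
  out2 <- collateralFeatures(t2)
  expect_equal(unname(out2["abnormal_voc_count"]), 3)
  expect_equal(unname(out2["filled_pause_count"]), 3)
})

test_that("extractFeatures yields exactly 60 keyed values, pure and order-invariant", {
  fw <- makeCleanTask("forward")
  bw <- makeCleanTask("backward")
  v <- extractFeatures(fw, bw, lexicon = lexD)
  expect_length(v, 60)
  expect_identical(names(v), speechFeatureNames())

  # purity: identical inputs give identical output
  expect_identical(v, extractFeatures(fw, bw, lexicon = lexD))

  # permuting the input event order changes nothing (events are sorted)
  fw2 <- fw
  perm <- sample(nrow(fw2@events))
  fw2 <- deriveSilences(AnnotatedTask("forward", fw2@events[perm, ],
                                      fw2@phoneEvents))
  expect_identical(extractFeatures(fw2, bw, lexicon = lexD), v)

  # an empty backward task leaves the 30 backward features missing
  expect_warning(
    v2 <- extractFeatures(fw, AnnotatedTask("backward"), lexicon = lexD),
    "no word events")
  expect_true(all(is.na(v2[ablationSubsets(names(v2))$backward])))
  expect_false(anyNA(v2[grep("forward__(?!intelligibility|f0|intensity)",
                             names(v2), perl = TRUE)]))
})

test_that("temporal rates tile the span when event classes cover it", {
  # numbers, errors, collateral and silences tile [0, 10] exactly
  labs <- c("1", "euh", "2", "[breath]", "3", "4")
  cats <- c("number", "filled_pause", "pronunciation_error_prolongation",
            "abnormal_breathing", "number", "number")
  starts <- c(0, 2, 3.5, 5, 7, 8.5)
  ends <- c(2, 3.5, 5, 7, 8.5, 10)
  task <- makeTask("forward", labels = c("1", "euh", "2", "[breath]", "3", "4"),
                   categories = cats, starts = starts, ends = ends)
  r <- rhythmFeatures(task, lexD)
  co <- collateralFeatures(task)
  # number events include the mispronounced "2"
  trSum <- unname(r["tr_numbers"] + r["tr_silences"] + co["tr_abnormal_voc"] +
                    co["tr_filled_pause"])
  expect_equal(trSum, 1, tolerance = 1e-9)
})
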
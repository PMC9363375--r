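# Validation protocol: repeated grouped participant-level splits (the
# exploration cohort is train-only; a fixed fraction of the validation cohort
# is held out each repeat), MAE and ICC(2,1) between observed and predicted
# scores, and paired Wilcoxon comparisons with Bonferroni correction.

#' Repeated grouped train/test split plans
#'
#' Every exploration-cohort participant is always in the training set. Per
#' repeat, the validation-cohort participants are split at the participant
#' level: `floor((1 - testFraction) n)` to training (the floor biases toward
#' larger training sets: 67 validation participants give 53 train / 14 test),
#' the rest to test. All visits of a participant land on the same side.
#'
#' @param participants `data.frame` with columns `participant_id`, `cohort`
#'   (`"exploration"` / `"validation"`), one row per participant.
#' @param nRepeats number of repeated splits (the protocol uses 50).
#' @param testFraction held-out fraction of the validation cohort (default
#'   0.2).
#' @param seed integer seed; plans are deterministic per (seed, repeat).
#' @return list of plans: each a list(repeat_index, train, test, seed).
#' @export
repeatedSplit <- function(participants, nRepeats = 50, testFraction = 0.2,
                          seed = 1) {
  stopifnot(all(c("participant_id", "cohort") %in% names(participants)))
  participants <- unique(participants[, c("participant_id", "cohort")])
  expl <- participants$participant_id[participants$cohort == "exploration"]
  val <- participants$participant_id[participants$cohort == "validation"]
  nTrainVal <- floor((1 - testFraction) * length(val))
  nTest <- length(val) - nTrainVal
  if (nTest < 1)
    stop("validation cohort too small for a non-empty test set", call. = FALSE)
  lapply(seq_len(nRepeats), function(r) {
    set.seed((seed %% 1000000L) * 1000L + r)
    shuffled <- sample(val)
    list(repeat_index = r,
         train = c(expl, shuffled[seq_len(nTrainVal)]),
         test = shuffled[(nTrainVal + 1):length(val)],
         seed = seed)
  })
}

#' Mean absolute error
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return mean of the absolute differences.
#' @export
maeScore <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch between observed and predicted", call. = FALSE)
  stopifnot(length(observed) >= 1)
  mean(abs(observed - predicted))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Treats observed and predicted scores as two raters of n targets and
#' decomposes the two-way table into between-target (MSR), between-rater
#' (MSC) and residual (MSE) mean squares:
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' with k = 2. A zero-variance column (e.g. the cohort-mean predictor) makes
#' absolute agreement undefined and raises an error.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3).
#' @return list of class `ICCResult`: icc, msr, msc, mse, n, k.
#' @export
icc21 <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch between observed and predicted", call. = FALSE)
  n <- length(observed)
  stopifnot(n >= 3)
  if (var(observed) == 0 || var(predicted) == 0)
    stop("ICC undefined: a rating column has zero standard deviation",
         call. = FALSE)
  k <- 2
  m <- cbind(observed, predicted)
  grand <- mean(m)
  rowM <- rowMeans(m)
  colM <- colMeans(m)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "ICCResult")
}

#' @export
print.ICCResult <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (n = %d targets, k = %d raters)\n",
              x$icc, x$n, x$k))
  invisible(x)
}

#' Paired model comparisons over repeated splits
#'
#' Two-sided Wilcoxon signed-rank tests on the paired per-repeat MAEs of
#' every model pair within every score, Bonferroni-corrected over all tests
#' in the report. All-zero difference vectors yield p = 1 with a warning.
#'
#' @param maeLists nested list: `maeLists[[score]][[kind]]` = numeric vector
#'   of per-repeat MAEs (equal lengths, same split plans).
#' @return `data.frame`: score, kind_a, kind_b, p_raw, p_bonferroni.
#' @export
compareModels <- function(maeLists) {
  rows <- list()
  for (score in names(maeLists)) {
    kinds <- names(maeLists[[score]])
    if (length(kinds) < 2) next
    for (i in seq_len(length(kinds) - 1))
      for (j in (i + 1):length(kinds)) {
        a <- maeLists[[score]][[kinds[i]]]
        b <- maeLists[[score]][[kinds[j]]]
        stopifnot(length(a) == length(b))
        if (all(a == b)) {
          warning(sprintf("%s: %s vs %s identical MAEs; p = 1", score,
                          kinds[i], kinds[j]), call. = FALSE)
          p <- 1
        } else {
          p <- suppressWarnings(
            wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          score = score, kind_a = kinds[i], kind_b = kinds[j], p_raw = p,
          stringsAsFactors = FALSE)
      }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Run the full repeated-split evaluation
#'
#' For each repeat and input-set kind, fits a predictor per target score on
#' the training visits and scores the held-out visits with MAE and ICC(2,1).
#' The ICC of the cohort-mean predictor is undefined (constant predictions)
#' and reported as NA.
#'
#' @param cohort a [SpeechCohort-class].
#' @param targets clinical score names to predict (default `"cuhdrs"`).
#' @param kinds input-set kinds, see [fitPredictor()].
#' @param nRepeats repeated splits (protocol default 50).
#' @param testFraction held-out fraction of the validation cohort.
#' @param budget a [searchBudget()].
#' @param seed integer seed.
#' @return list of class `EvaluationReport`: `mae` and `icc` (nested
#'   score -> kind -> per-repeat vectors), `comparisons`, `plans`.
#' @export
evaluateModels <- function(cohort, targets = "cuhdrs",
                           kinds = c("speech_plus_demographics",
                                     "demographics_only", "cohort_mean"),
                           nRepeats = 50, testFraction = 0.2,
                           budget = searchBudget(), seed = 1) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  plans <- repeatedSplit(cd, nRepeats = nRepeats,
                         testFraction = testFraction, seed = seed)
  mae <- icc <- lapply(setNames(targets, targets), function(t)
    lapply(setNames(kinds, kinds), function(k) numeric(nRepeats)))
  for (r in seq_len(nRepeats)) {
    plan <- plans[[r]]
    trainIdx <- which(cd$participant_id %in% plan$train)
    testIdx <- which(cd$participant_id %in% plan$test)
    for (target in targets) {
      for (kind in kinds) {
        fit <- fitPredictor(cohort[, trainIdx], target = target, kind = kind,
                            budget = budget,
                            seed = seed * 1000L + r)
        pred <- predictScores(fit, cohort[, testIdx])
        obs <- cd[[target]][testIdx]
        mae[[target]][[kind]][r] <- maeScore(obs, pred)
        icc[[target]][[kind]][r] <- if (var(pred) == 0) NA_real_ else
          icc21(obs, pred)$icc
      }
    }
  }
  structure(list(mae = mae, icc = icc, comparisons = compareModels(mae),
                 plans = plans, targets = targets, kinds = kinds),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: %d repeats, %d score(s) x %d input set(s)\n",
              length(x$plans), length(x$targets), length(x$kinds)))
  for (t in x$targets) {
    for (k in x$kinds) {
      m <- x$mae[[t]][[k]]
      ic <- x$icc[[t]][[k]]
      cat(sprintf("  %-10s %-26s MAE %.3f +/- %.3f  ICC %s\n", t, k,
                  mean(m), sd(m),
                  if (all(is.na(ic))) "NA (constant predictions)"
                  else sprintf("%.3f +/- %.3f", mean(ic, na.rm = TRUE),
                               sd(ic, na.rm = TRUE))))
    }
  }
  invisible(x)
}

#' Long-format export of an evaluation report
#'
#' One row per (score, kind, repeat) with the test MAE and ICC; suitable for
#' boxplots.
#'
#' @param report an `EvaluationReport`.
#' @return `data.frame`.
#' @export
reportToLong <- function(report) {
  rows <- list()
  for (t in report$targets)
    for (k in report$kinds) {
      n <- length(report$mae[[t]][[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        score = t, kind = k, repeat_index = seq_len(n),
        mae = report$mae[[t]][[k]], icc = report$icc[[t]][[k]],
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
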
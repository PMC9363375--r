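# Bounded portfolio model search. The automated-ML search of the original
# protocol is replaced by a declared, reproducible random search with the
# same budget semantics (workers x floor(total / per-fit) candidate models
# minimum), grouped 5-fold cross-validation minimising MAE, and a greedy
# weighted ensemble of the best candidates (Caruana-style, with
# replacement). One model is selected independently per clinical score.

INPUT_KINDS <- c("speech_plus_demographics", "demographics_only",
                 "cohort_mean", "forward_only", "backward_only")

#' Model-search budget
#'
#' Budget semantics mirror a parallel wall-clock search: with the defaults
#' (120 s per score, 30 s per fit, 24 workers) at least
#' \code{24 * floor(120/30) = 96} candidate models are evaluated. The search
#' here is count-based: exactly [minCandidateCount()] candidates are drawn
#' from the portfolio.
#'
#' @param totalBudget seconds per clinical score (default 120).
#' @param perFitLimit seconds per model training (default 30).
#' @param workers parallel workers the budget assumes (default 24).
#' @param ensembleSize number of top candidates combined (default 50).
#' @return budget list.
#' @export
searchBudget <- function(totalBudget = 120, perFitLimit = 30, workers = 24,
                         ensembleSize = 50) {
  stopifnot(totalBudget > 0, perFitLimit > 0, perFitLimit <= totalBudget,
            workers >= 1, ensembleSize >= 1)
  list(totalBudget = totalBudget, perFitLimit = perFitLimit,
       workers = workers, ensembleSize = ensembleSize)
}

#' Minimum number of candidate models under a budget
#'
#' \code{workers * floor(totalBudget / perFitLimit)}.
#'
#' @param budget a [searchBudget()].
#' @return integer count.
#' @export
minCandidateCount <- function(budget) {
  budget$workers * floor(budget$totalBudget / budget$perFitLimit)
}

#' Forward / backward ablation subsets
#'
#' Splits a full 60-key feature vector (or its names) into the two disjoint
#' 30-key per-task subsets.
#'
#' @param vector named 60-feature vector, or the 60 key names.
#' @return list with `forward` and `backward` components.
#' @export
ablationSubsets <- function(vector) {
  keys <- if (is.character(vector)) vector else names(vector)
  if (!setequal(keys, speechFeatureNames()))
    stop("expected exactly the 60 <task>__<feature> keys", call. = FALSE)
  pick <- function(task) {
    sel <- keys[startsWith(keys, paste0(task, "__"))]
    if (is.character(vector)) sel else vector[sel]
  }
  list(forward = pick("forward"), backward = pick("backward"))
}

# ---- design matrices -------------------------------------------------------

.demoBlock <- function(cd) {
  cbind(sex_m = as.numeric(cd$sex == "M"), age = cd$age, cag = cd$cag,
        dbs = cd$dbs)
}

.designMatrix <- function(cohort, kind) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  feat <- t(SummarizedExperiment::assay(cohort, "features"))
  switch(kind,
    speech_plus_demographics = cbind(feat, .demoBlock(cd)),
    demographics_only = .demoBlock(cd),
    cohort_mean = matrix(nrow = nrow(cd), ncol = 0),
    forward_only = feat[, ablationSubsets(colnames(feat))$forward,
                        drop = FALSE],
    backward_only = feat[, ablationSubsets(colnames(feat))$backward,
                         drop = FALSE],
    stop("unknown input kind: ", kind, call. = FALSE))
}

# ---- preprocessing ---------------------------------------------------------

.fitRecipe <- function(X) {
  med <- apply(X, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  keep <- sig > 0
  list(medians = med, mu = mu, sigma = sig, keep = keep)
}

.applyRecipe <- function(recipe, X) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- recipe$medians[j]
  X <- sweep(X, 2, recipe$mu, "-")
  X <- sweep(X[, recipe$keep, drop = FALSE], 2,
             recipe$sigma[recipe$keep], "/")
  X
}

# ---- portfolio -------------------------------------------------------------

.samplePortfolio <- function(nCand) {
  fams <- sample(c("enet", "knn", "svr", "rf", "rpart"), nCand,
                 replace = TRUE, prob = c(0.35, 0.15, 0.2, 0.15, 0.15))
  lapply(seq_len(nCand), function(i) {
    fam <- fams[i]
    params <- switch(fam,
      enet = list(alpha = runif(1), loglam = runif(1, -3.5, 0.5)),
      knn = list(k = sample(3:15, 1)),
      svr = list(cost = 10^runif(1, -1, 2), gamma = 10^runif(1, -3, -0.5),
                 epsilon = runif(1, 0.05, 0.3)),
      rf = list(mtryFrac = runif(1, 0.2, 0.9),
                minNode = sample(2:10, 1), numTrees = 150L),
      rpart = list(cp = 10^runif(1, -4, -1), minsplit = sample(5:20, 1)))
    list(family = fam, params = params, seed = sample.int(1e6, 1))
  })
}

.fitOne <- function(cand, X, y) {
  p <- cand$params
  fit <- switch(cand$family,
    enet = glmnet::glmnet(X, y, alpha = p$alpha,
                          lambda = 10^p$loglam * sd(y)),
    knn = list(X = X, y = y, k = min(p$k, nrow(X))),
    svr = e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                     cost = p$cost, gamma = p$gamma,
                     epsilon = p$epsilon * sd(y)),
    rf = ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = p$numTrees,
      mtry = max(1L, floor(p$mtryFrac * ncol(X))),
      min.node.size = p$minNode, seed = cand$seed, num.threads = 1),
    rpart = rpart::rpart(y ~ ., data = data.frame(X, y = y),
                         control = rpart::rpart.control(
                           cp = p$cp, minsplit = p$minsplit, xval = 0)))
  list(family = cand$family, params = p, fit = fit,
       featureNames = colnames(X))
}

.predictOne <- function(member, X) {
  switch(member$family,
    enet = as.numeric(predict(member$fit, newx = X)),
    knn = {
      tr <- member$fit$X
      d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
      apply(d2, 1, function(row) {
        nn <- order(row)[seq_len(member$fit$k)]
        mean(member$fit$y[nn])
      })
    },
    svr = as.numeric(predict(member$fit, X)),
    rf = predict(member$fit, data = as.data.frame(X),
                 num.threads = 1)$predictions,
    rpart = as.numeric(predict(member$fit, newdata = as.data.frame(X))))
}

# greedy forward selection with replacement over out-of-fold predictions;
# returns indices (with multiplicity) whose mean minimises OOF MAE, never
# worse than the best single candidate
.greedyEnsemble <- function(oof, y, poolIdx, iters) {
  best <- poolIdx[1]
  sel <- c(best)
  acc <- oof[, best]
  bestSel <- sel
  bestMae <- mean(abs(y - acc))
  for (it in seq_len(iters - 1)) {
    errs <- vapply(poolIdx, function(j)
      mean(abs(y - (acc * length(sel) + oof[, j]) / (length(sel) + 1))),
      numeric(1))
    j <- poolIdx[which.min(errs)]
    acc <- (acc * length(sel) + oof[, j]) / (length(sel) + 1)
    sel <- c(sel, j)
    if (min(errs) < bestMae - 1e-12) {
      bestMae <- min(errs)
      bestSel <- sel
    }
  }
  list(members = bestSel, mae = bestMae)
}

#' Fit a clinical-score predictor with the bounded portfolio search
#'
#' Draws [minCandidateCount()] candidate configurations from the portfolio
#' (elastic-net, k-nearest-neighbour, RBF support-vector, random-forest and
#' CART regressors with sampled hyperparameters), scores each by grouped
#' 5-fold cross-validated MAE (participants never straddle folds), and
#' combines the top `ensembleSize` candidates by greedy weighted ensembling
#' on the out-of-fold predictions. Deterministic given `seed`. The
#' `cohort_mean` kind bypasses the search and predicts the training-set mean
#' of the target; a zero-variance target falls back to it with a warning.
#'
#' @param cohort a [SpeechCohort-class] of training visits.
#' @param target clinical score name (column of `colData`).
#' @param kind input-set kind: `r paste(INPUT_KINDS, collapse = ", ")`.
#' @param budget a [searchBudget()].
#' @param seed integer seed.
#' @return a [TrainedPredictor-class].
#' @export
fitPredictor <- function(cohort, target, kind = "speech_plus_demographics",
                         budget = searchBudget(), seed = 1) {
  kind <- match.arg(kind, INPUT_KINDS)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  y <- cd[[target]]
  if (is.null(y)) stop("unknown target score: ", target, call. = FALSE)
  if (anyNA(y)) stop("missing target values in training data", call. = FALSE)
  clip <- SCORE_RANGES[[target]]
  if (is.null(clip)) clip <- c(-Inf, Inf)

  meanPredictor <- function() {
    new("TrainedPredictor", target = target, inputKind = kind,
        members = list(list(family = "mean", params = list(),
                            fit = mean(y), featureNames = character())),
        weights = 1, recipe = list(),
        metadata = list(seed = seed, nCandidates = 0L,
                        cvMae = mean(abs(y - mean(y))), clipRange = clip))
  }
  if (kind == "cohort_mean") return(meanPredictor())
  if (var(y) == 0) {
    warning("target has zero variance; falling back to the cohort mean",
            call. = FALSE)
    return(meanPredictor())
  }
  if (nrow(cd) < 20)
    stop("at least 20 training visits required", call. = FALSE)

  set.seed(seed)
  Xraw <- .designMatrix(cohort, kind)
  recipe <- .fitRecipe(Xraw)
  X <- .applyRecipe(recipe, Xraw)

  # grouped 5-fold assignment at the participant level
  parts <- unique(cd$participant_id)
  foldOfPart <- setNames(sample(rep_len(1:5, length(parts))), parts)
  fold <- foldOfPart[as.character(cd$participant_id)]

  nCand <- minCandidateCount(budget)
  cands <- .samplePortfolio(nCand)
  oof <- matrix(NA_real_, nrow(X), nCand)
  for (ci in seq_len(nCand)) {
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (var(y[tr]) == 0) {
        oof[!tr, ci] <- mean(y[tr])
        next
      }
      m <- .fitOne(cands[[ci]], X[tr, , drop = FALSE], y[tr])
      oof[!tr, ci] <- .predictOne(m, X[!tr, , drop = FALSE])
    }
  }
  cvMae <- colMeans(abs(oof - y))
  pool <- order(cvMae)[seq_len(min(budget$ensembleSize, nCand))]
  ens <- .greedyEnsemble(oof, y, pool, iters = min(budget$ensembleSize, 25L))

  tab <- table(ens$members)
  memberIdx <- as.integer(names(tab))
  weights <- as.numeric(tab) / sum(tab)
  members <- lapply(memberIdx, function(ci) .fitOne(cands[[ci]], X, y))

  new("TrainedPredictor", target = target, inputKind = kind,
      members = members, weights = weights,
      recipe = recipe,
      metadata = list(seed = seed, nCandidates = nCand, cvMae = ens$mae,
                      bestSingleCvMae = min(cvMae), clipRange = clip,
                      foldOfPart = foldOfPart))
}

#' Predict clinical scores for new visits
#'
#' Applies the stored preprocessing recipe and the weighted ensemble;
#' predictions are clipped to the target score's valid range.
#'
#' @param object a [TrainedPredictor-class].
#' @param cohort a [SpeechCohort-class] of visits to score.
#' @return numeric vector of predictions.
#' @export
predictScores <- function(object, cohort) {
  if (length(object@members) == 1 && object@members[[1]]$family == "mean") {
    n <- ncol(cohort)
    pred <- rep(object@members[[1]]$fit, n)
  } else {
    Xraw <- .designMatrix(cohort, object@inputKind)
    X <- .applyRecipe(object@recipe, Xraw)
    preds <- vapply(object@members, function(m) .predictOne(m, X),
                    numeric(nrow(X)))
    pred <- as.numeric(as.matrix(preds) %*% object@weights)
  }
  clip <- object@metadata$clipRange
  pmin(pmax(pred, clip[1]), clip[2])
}

#' Elastic-net feature importance per clinical score
#'
#' Fits a linear elastic-net regression of the target on the standardised
#' speech features (cross-validated regularisation strength, fixed folds for
#' determinism), flips the coefficient signs so that a larger weight always
#' reads as greater clinical impairment, and z-scores the weights across
#' features within the score.
#'
#' @param cohort a [SpeechCohort-class].
#' @param target clinical score name.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed integer seed (controls CV folds).
#' @return list: `weights` (z-scored, named), `raw` (sign-adjusted
#'   coefficients before z-scoring).
#' @export
elasticnetImportance <- function(cohort, target, alpha = 0.5, seed = 1) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  y <- cd[[target]]
  Xraw <- t(SummarizedExperiment::assay(cohort, "features"))
  recipe <- .fitRecipe(Xraw)
  X <- .applyRecipe(recipe, Xraw)
  set.seed(seed)
  foldid <- sample(rep_len(1:5, nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid)
  beta <- as.numeric(coef(cvfit, s = "lambda.1se"))[-1]
  names(beta) <- colnames(X)
  sign <- unname(SCORE_IMPAIRMENT_SIGN[target])
  if (is.na(sign)) sign <- 1
  raw <- setNames(rep(0, ncol(Xraw)), colnames(Xraw))
  raw[names(beta)] <- beta * sign
  z <- if (sd(raw) == 0) raw * 0 else (raw - mean(raw)) / sd(raw)
  list(weights = z, raw = raw)
}
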
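# Feature / striatal-volume association screening. TICe screens for
# significance (high power), MICe measures strength (high equitability);
# Pearson and Spearman are descriptive companions. Family-wise error over the
# screened variables is controlled by maximum-statistic permutation: the same
# volume permutation is applied to every variable in a round, so the
# correction respects the inter-feature correlation structure.

#' Association screening configuration
#'
#' @param alphaExponent grid-size exponent: the grid bound is
#'   \code{B(n) = n^alphaExponent} (default 0.6, the estimator's published
#'   default).
#' @param maxClumpsFactor candidate-boundary multiplier for the dynamic
#'   programme (default 5).
#' @param nPermutations permutation rounds for p-values (default 2000,
#'   minimum 100).
#' @param fwerAlpha family-wise error level used when reporting significance.
#' @param bMax optional explicit grid bound replacing \code{n^alphaExponent}
#'   (0 = use the exponent); mainly for small-sample validation against
#'   exhaustive enumeration.
#' @param seed integer seed for the permutation draws.
#' @return configuration list.
#' @export
associationConfig <- function(alphaExponent = 0.6, maxClumpsFactor = 5,
                              nPermutations = 2000, fwerAlpha = 0.05,
                              bMax = 0, seed = 1) {
  stopifnot(alphaExponent > 0, alphaExponent < 1, nPermutations >= 100,
            maxClumpsFactor >= 1)
  list(alphaExponent = alphaExponent, maxClumpsFactor = maxClumpsFactor,
       nPermutations = as.integer(nPermutations), fwerAlpha = fwerAlpha,
       bMax = as.integer(bMax), seed = as.integer(seed))
}

.checkPair <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    warning("constant input vector; information coefficient is 0 by convention",
            call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Maximal information coefficient (MICe)
#'
#' Equicharacteristic-matrix estimator: over all grid shapes (k, l) with
#' \code{k l <= B(n)}, one axis is mass-equipartitioned and the other
#' optimised by dynamic programming over clump boundaries; each entry is the
#' maximal mutual information normalised by \code{log2 min(k, l)}. MICe is
#' the maximum entry. Both orientations are computed and combined, making
#' the statistic symmetric.
#'
#' @param x,y numeric vectors (n >= 10, finite).
#' @param cfg an [associationConfig()].
#' @return MICe in \code{[0, 1]}.
#' @export
miceStat <- function(x, y, cfg = associationConfig()) {
  if (!.checkPair(x, y)) return(0)
  .cpp_mine(x, y, cfg$alphaExponent, cfg$maxClumpsFactor, cfg$bMax)$mice
}

#' Total information coefficient (TICe)
#'
#' Sum of the characteristic-matrix entries over all admissible grid shapes;
#' shares the matrix computation with [miceStat()] and always satisfies
#' \code{tice >= mice}.
#'
#' @inheritParams miceStat
#' @return non-negative statistic.
#' @export
ticeStat <- function(x, y, cfg = associationConfig()) {
  if (!.checkPair(x, y)) return(0)
  .cpp_mine(x, y, cfg$alphaExponent, cfg$maxClumpsFactor, cfg$bMax)$tice
}

#' Full characteristic matrix (for validation)
#'
#' @inheritParams miceStat
#' @return matrix indexed by grid shape; entry \code{[k+1, l+1]} corresponds
#'   to k x-bins and l y-bins, NA outside the admissible region.
#' @export
characteristicMatrix <- function(x, y, cfg = associationConfig()) {
  .cpp_char_matrix(x, y, cfg$alphaExponent, cfg$maxClumpsFactor, cfg$bMax)
}

#' Maximum-statistic family-wise error correction
#'
#' Given the observed statistic of each variable and, per permutation round,
#' the maximum statistic over all variables (the same permutation applied to
#' every variable within a round), the adjusted p-value of variable v is
#' \code{(1 + #\{rounds: max >= observed(v)\}) / (nPermutations + 1)}, the
#' +1-smoothed estimator that never reports an exact zero.
#'
#' @param observed named numeric vector of observed statistics.
#' @param permutedMax per-round maximum statistics (length = rounds, >= 100).
#' @return adjusted p-value per variable.
#' @export
maxStatCorrection <- function(observed, permutedMax) {
  stopifnot(length(permutedMax) >= 100)
  vapply(observed, function(o)
    (1 + sum(permutedMax >= o)) / (length(permutedMax) + 1), numeric(1))
}

#' Striatal volume as a percentage of intracranial volume
#'
#' \code{100 (caudate + putamen + ventral striatum) / eTIV}, all volumes in
#' the same unit (mL), hemispheres already summed.
#'
#' @param caudate,putamen,ventralStriatum structure volumes (> 0).
#' @param etiv estimated total intracranial volume (> striatal sum).
#' @return percentage (vectorised).
#' @export
striatalVolumePercent <- function(caudate, putamen, ventralStriatum, etiv) {
  if (any(c(caudate, putamen, ventralStriatum, etiv) <= 0))
    stop("volumes must be positive", call. = FALSE)
  s <- caudate + putamen + ventralStriatum
  if (any(etiv <= s))
    stop("eTIV must exceed the striatal sum", call. = FALSE)
  100 * s / etiv
}

#' Screen speech features and clinical variables against striatal volume
#'
#' For every speech feature and clinical variable: TICe with its raw
#' permutation p-value, the maximum-statistic adjusted p (correction pooled
#' within the speech-feature family and, separately, within the clinical
#' family), MICe, Pearson r and Spearman rho versus the striatal volume
#' percentage. Rows are sorted by adjusted p.
#'
#' @param features numeric matrix, participants x speech features.
#' @param clinical numeric matrix or data.frame, participants x clinical
#'   variables (may have zero columns).
#' @param volumes striatal volume percentage per participant.
#' @param cfg an [associationConfig()]; `cfg$seed` drives the permutations.
#' @return `data.frame`: variable, family, tice, tice_p, adjusted_p, mice,
#'   pearson_r, spearman_rho.
#' @export
striatalScreen <- function(features, clinical, volumes,
                           cfg = associationConfig()) {
  features <- as.matrix(features)
  clinical <- if (is.null(clinical)) matrix(nrow = nrow(features), ncol = 0)
              else as.matrix(clinical)
  stopifnot(nrow(features) == length(volumes),
            nrow(clinical) == length(volumes))
  ok <- complete.cases(features) & complete.cases(clinical) &
    is.finite(volumes)
  if (sum(ok) < 10)
    stop(sprintf("only %d participants with complete features and volumes (>= 10 required)",
                 sum(ok)), call. = FALSE)
  features <- features[ok, , drop = FALSE]
  clinical <- clinical[ok, , drop = FALSE]
  volumes <- volumes[ok]
  n <- length(volumes)

  X <- cbind(features, clinical)
  fam <- rep(c("speech", "clinical"), c(ncol(features), ncol(clinical)))
  const <- apply(X, 2, var) == 0
  if (any(const))
    warning("constant variable(s) score 0: ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)

  set.seed(cfg$seed)
  perms <- vapply(seq_len(cfg$nPermutations), function(i) sample.int(n),
                  integer(n))
  res <- .cpp_mine_batch(X, volumes, cfg$alphaExponent, cfg$maxClumpsFactor,
                         cfg$bMax, perms)
  tice <- ifelse(const, 0, res$tice)
  mice <- ifelse(const, 0, res$mice)
  ticePerm <- res$tice_perm
  ticePerm[const, ] <- 0

  rawP <- vapply(seq_len(ncol(X)), function(j)
    (1 + sum(ticePerm[j, ] >= tice[j])) / (cfg$nPermutations + 1), numeric(1))
  adjP <- rep(NA_real_, ncol(X))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    famMax <- apply(ticePerm[idx, , drop = FALSE], 2, max)
    adjP[idx] <- maxStatCorrection(tice[idx], famMax)
  }

  out <- data.frame(
    variable = colnames(X), family = fam,
    tice = tice, tice_p = rawP, adjusted_p = adjP, mice = mice,
    pearson_r = apply(X, 2, function(v) if (var(v) == 0) NA_real_ else
      cor(v, volumes)),
    spearman_rho = apply(X, 2, function(v) if (var(v) == 0) NA_real_ else
      cor(v, volumes, method = "spearman")),
    significant = adjP <= cfg$fwerAlpha,
    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$tice_p), ]
  rownames(out) <- NULL
  out
}
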
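# Sequence-error metrics against the counting target: Levenshtein edit
# distance and Ratcliff-Obershelp ("gestalt") similarity over token lists.

#' Levenshtein distance between token sequences
#'
#' Minimal number of single-token insertions, deletions and substitutions
#' (unit costs) transforming `a` into `b`.
#'
#' @param a,b character (or atomic) vectors of tokens.
#' @return non-negative integer distance.
#' @export
levenshteinDist <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    curr <- integer(m + 1L)
    curr[1] <- i
    for (j in seq_len(m)) {
      curr[j + 1L] <- min(prev[j + 1L] + 1L,
                          curr[j] + 1L,
                          prev[j] + (a[i] != b[j]))
    }
    prev <- curr
  }
  prev[m + 1L]
}

#' Ratcliff-Obershelp similarity between token sequences
#'
#' Recursively locates the longest common contiguous block, recurses on the
#' unmatched flanks, and returns \code{2 K / (|a| + |b|)} where K is the total
#' number of matched tokens. Two empty sequences are defined to be identical
#' (similarity 1).
#'
#' @param a,b character (or atomic) vectors of tokens.
#' @return similarity in \code{[0, 1]}.
#' @export
gestaltSimilarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  2 * .gestaltMatches(a, b) / (length(a) + length(b))
}

# longest common contiguous block (first-leftmost on ties, as in the
# classical formulation), then recurse left and right of it
.gestaltMatches <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  best <- 0L; bi <- 0L; bj <- 0L
  # DP over suffix run lengths
  prev <- integer(m)
  for (i in seq_len(n)) {
    curr <- integer(m)
    match <- a[i] == b
    for (j in seq_len(m)) {
      if (match[j]) {
        curr[j] <- (if (j > 1) prev[j - 1L] else 0L) + 1L
        if (curr[j] > best) {
          best <- curr[j]; bi <- i; bj <- j
        }
      }
    }
    prev <- curr
  }
  if (best == 0L) return(0L)
  best +
    .gestaltMatches(a[seq_len(bi - best)], b[seq_len(bj - best)]) +
    .gestaltMatches(if (bi < n) a[(bi + 1L):n] else character(0),
                    if (bj < m) b[(bj + 1L):m] else character(0))
}
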
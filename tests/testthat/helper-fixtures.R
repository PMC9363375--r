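# Shared fixtures and independent oracles. All fixtures are built in code.

.cohortCache <- new.env(parent = emptyenv())

# default synthetic cohort, built once per test session
defaultCohort <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- buildCohort(seed = seed)
  .cohortCache[[key]]
}

# small hand-built annotated task: labels/categories/times fully specified
makeTask <- function(task = "forward",
                     labels, categories, starts, ends,
                     phoneLabels = character(0), phoneStarts = numeric(0),
                     phoneEnds = numeric(0), minSilence = 0.1) {
  ev <- data.frame(label = labels, category = categories,
                   start = starts, end = ends, stringsAsFactors = FALSE)
  ph <- data.frame(label = phoneLabels, category = rep("number",
                                                       length(phoneLabels)),
                   start = phoneStarts, end = phoneEnds,
                   stringsAsFactors = FALSE)
  deriveSilences(AnnotatedTask(task, ev, ph), minSilence = minSilence)
}

# a clean forward recitation: n numbers of fixed duration and gap
makeCleanTask <- function(task = "forward", n = 20, dur = 0.4, gap = 0.3,
                          lexicon = numberLexicon("digits")) {
  ord <- if (task == "forward") seq_len(n) else rev(seq_len(n))
  starts <- (seq_len(n) - 1) * (dur + gap)
  phones <- lapply(seq_len(n), function(i) {
    ph <- strsplit(lexicon$phones[match(ord[i], lexicon$number)], " ")[[1]]
    edges <- seq(starts[i], starts[i] + dur, length.out = length(ph) + 1)
    data.frame(label = ph, category = "number",
               start = edges[-length(edges)], end = edges[-1],
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, phones)
  makeTask(task, labels = as.character(ord),
           categories = rep("number", n),
           starts = starts, ends = starts + dur,
           phoneLabels = ph$label, phoneStarts = ph$start,
           phoneEnds = ph$end)
}

# --- independent oracles ----------------------------------------------------

# Levenshtein by the naive recursive definition (memoised)
levOracle <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + (a[i] != b[j]))
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Ratcliff-Obershelp matched-token count by direct definition: scan all
# index pairs for the longest common contiguous block, recurse on flanks
gestaltOracleK <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    len <- 0L
    while (i + len <= n && j + len <= m && a[i + len] == b[j + len])
      len <- len + 1L
    if (len > best) { best <- len; bi <- i; bj <- j }
  }
  if (best == 0L) return(0L)
  best + gestaltOracleK(a[seq_len(bi - 1)], b[seq_len(bj - 1)]) +
    gestaltOracleK(if (bi + best <= n) a[(bi + best):n] else character(0),
                   if (bj + best <= m) b[(bj + best):m] else character(0))
}

gestaltOracle <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  2 * gestaltOracleK(a, b) / (length(a) + length(b))
}

# ICC(2,1) through R's ANOVA decomposition (aov mean squares)
iccOracle <- function(obs, pred) {
  n <- length(obs)
  d <- data.frame(y = c(obs, pred),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Exhaustive characteristic-matrix oracle for small n: all cut positions on
# the optimised axis (inputs assumed tie-free), the same mass equipartition
# on the fixed axis.
entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

miOfPartition <- function(binAssign, rowAssign) {
  tab <- table(binAssign, rowAssign)
  p <- tab / sum(tab)
  entropyBits(rowSums(p)) + entropyBits(colSums(p)) - entropyBits(as.numeric(p))
}

# max MI over all partitions of the x axis into at most k contiguous bins
maxMIExhaustive <- function(x, rows, k) {
  n <- length(x)
  ord <- order(x)
  rowsOrd <- rows[ord]
  cuts <- seq_len(n - 1)  # cut after position i (tie-free x)
  best <- 0
  for (t in 2:k) {
    if (t - 1 > length(cuts)) break
    for (cmb in asplit(utils::combn(cuts, t - 1), 2)) {
      binAssign <- findInterval(seq_len(n), c(cmb + 0.5)) # 0..t-1
      best <- max(best, miOfPartition(binAssign, rowsOrd))
    }
  }
  best
}

mineOracle <- function(x, y, B) {
  equip <- function(v, l) hdspeech:::.cpp_equipartition(v, l)
  mice <- 0; tice <- 0
  for (k in 2:B) for (l in 2:B) {
    if (k * l > B) next
    i1 <- maxMIExhaustive(x, equip(y, l), k)
    i2 <- maxMIExhaustive(y, equip(x, k), l)
    entry <- max(i1, i2) / log2(min(k, l))
    mice <- max(mice, entry)
    tice <- tice + entry
  }
  list(mice = mice, tice = tice)
}
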
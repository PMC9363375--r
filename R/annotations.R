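# Praat TextGrid I/O and annotation utilities.
#
# Both the long ("ooTextFile") and short text dialects are accepted, in UTF-8
# or UTF-16 (BOM-detected). Only interval tiers are read. Event categories are
# resolved from the label itself: an explicit "label#category" marker wins,
# then the configured label-to-category table, then membership in the number
# lexicon (category "number"); anything else is a validation error.

.detectEncoding <- function(path) {
  bom <- readBin(path, "raw", n = 2L)
  if (length(bom) == 2L && bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE))
    return("UTF-16LE")
  if (length(bom) == 2L && bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF))
    return("UTF-16BE")
  "UTF-8"
}

.readTextGridLines <- function(path) {
  enc <- .detectEncoding(path)
  con <- file(path, encoding = enc)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.tgStop <- function(line, fmt, ...) {
  stop(sprintf("TextGrid parse error at line %d: %s", line, sprintf(fmt, ...)),
       call. = FALSE)
}

.tgNum <- function(tok, line) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) .tgStop(line, "expected a number, got '%s'", tok)
  v
}

# Unquote a Praat string, collapsing doubled quotes.
.tgUnquote <- function(s) gsub('""', '"', sub('^"', "", sub('"$', "", s)))

.parseLongTextGrid <- function(lines) {
  tiers <- list()
  cur <- NULL
  pend <- list(xmin = NA_real_, xmax = NA_real_)
  inIntervals <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (grepl("^item \\[[0-9]+\\]", ln)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
      cur <- list(name = "", class = "", intervals = list())
      inIntervals <- FALSE
    } else if (grepl("^class\\s*=", ln) && !is.null(cur)) {
      cur$class <- .tgUnquote(trimws(sub("^class\\s*=", "", ln)))
    } else if (grepl("^name\\s*=", ln) && !is.null(cur)) {
      cur$name <- .tgUnquote(trimws(sub("^name\\s*=", "", ln)))
    } else if (grepl("^intervals(:| \\[)", ln)) {
      inIntervals <- TRUE
      pend <- list(xmin = NA_real_, xmax = NA_real_)
    } else if (inIntervals && grepl("^xmin\\s*=", ln)) {
      pend$xmin <- .tgNum(trimws(sub("^xmin\\s*=", "", ln)), i)
    } else if (inIntervals && grepl("^xmax\\s*=", ln)) {
      pend$xmax <- .tgNum(trimws(sub("^xmax\\s*=", "", ln)), i)
    } else if (inIntervals && grepl("^text\\s*=", ln)) {
      if (is.na(pend$xmin) || is.na(pend$xmax))
        .tgStop(i, "interval text before its xmin/xmax")
      txt <- .tgUnquote(trimws(sub("^text\\s*=", "", ln)))
      cur$intervals[[length(cur$intervals) + 1L]] <-
        list(xmin = pend$xmin, xmax = pend$xmax, text = txt)
      pend <- list(xmin = NA_real_, xmax = NA_real_)
    }
  }
  if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
  tiers
}

.parseShortTextGrid <- function(lines) {
  keep <- nzchar(trimws(lines)) & seq_along(lines) > 2
  toks <- trimws(lines[keep])
  lnum <- seq_along(lines)[keep]
  i <- 1L
  need <- function() {
    if (i > length(toks)) .tgStop(length(lines), "unexpected end of file")
    toks[i]
  }
  # global xmin, xmax, <exists>, size
  i <- i + 2L
  if (!grepl("exists", need())) .tgStop(lnum[i], "expected '<exists>' flag")
  i <- i + 1L
  size <- as.integer(.tgNum(need(), lnum[i])); i <- i + 1L
  tiers <- vector("list", size)
  for (t in seq_len(size)) {
    cls <- .tgUnquote(need()); i <- i + 1L
    nm <- .tgUnquote(need()); i <- i + 1L
    i <- i + 2L  # tier xmin, xmax
    nint <- as.integer(.tgNum(need(), lnum[i])); i <- i + 1L
    ivs <- vector("list", nint)
    for (j in seq_len(nint)) {
      a <- .tgNum(need(), lnum[i]); i <- i + 1L
      b <- .tgNum(need(), lnum[i]); i <- i + 1L
      txt <- .tgUnquote(need()); i <- i + 1L
      ivs[[j]] <- list(xmin = a, xmax = b, text = txt)
    }
    tiers[[t]] <- list(name = nm, class = cls, intervals = ivs)
  }
  tiers
}

.parseTextGrid <- function(path) {
  lines <- .readTextGridLines(path)
  if (length(lines) < 3 || !grepl("ooTextFile", lines[1]))
    .tgStop(1L, "not a Praat TextGrid ('File type = \"ooTextFile\"' missing)")
  if (!grepl("TextGrid", lines[2]))
    .tgStop(2L, "object class is not TextGrid")
  if (any(grepl("^\\s*item\\s*\\[", lines))) .parseLongTextGrid(lines)
  else .parseShortTextGrid(lines)
}

#' Default annotation configuration
#'
#' Reads the bundled annotation config (tier names, label-to-category table,
#' minimum-silence threshold) or a user-supplied YAML file with the same
#' `tiers` / `labels` / `silence` sections.
#'
#' @param path YAML config path; default = the bundled config.
#' @return a list with elements `tiers`, `labels`, `silence`.
#' @export
annotationConfig <- function(path = system.file("extdata",
                                                "annotation_config.yaml",
                                                package = "hdspeech")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$tiers), is.list(cfg$labels), is.list(cfg$silence))
  cfg
}

#' Number lexicon
#'
#' Maps number tokens 1..20 to word labels and canonical phone sequences.
#' `"french"` loads the bundled SAMPA lexicon used for real recordings;
#' `"digits"` is the abstract synthesis lexicon (labels `"1"`..`"20"`, phones
#' `P01`..`P40`, two per number).
#'
#' @param language `"french"` or `"digits"`.
#' @return `data.frame` with columns number, word, phones (space-separated).
#' @export
numberLexicon <- function(language = c("digits", "french")) {
  language <- match.arg(language)
  if (language == "french") {
    lex <- read.csv(system.file("extdata", "lexicon_fr.csv",
                                package = "hdspeech"),
                    stringsAsFactors = FALSE)
  } else {
    lex <- data.frame(
      number = 1:20, word = as.character(1:20),
      phones = vapply(1:20, function(n)
        paste(sprintf("P%02d", c(2 * n - 1, 2 * n)), collapse = " "),
        character(1)),
      stringsAsFactors = FALSE)
  }
  lex
}

#' Target recitation sequence for a counting task
#'
#' Forward counting targets the numbers 1..20 in order; backward counting the
#' reverse. The phone-level target concatenates the lexicon phones of the
#' target numbers in task order.
#'
#' @param task `"forward"` or `"backward"`.
#' @param lexicon a [numberLexicon()] table.
#' @return list with `numbers` (character labels), `phones` (character).
#' @export
targetSequence <- function(task = c("forward", "backward"),
                           lexicon = numberLexicon()) {
  task <- match.arg(task)
  ord <- if (task == "forward") 1:20 else 20:1
  idx <- match(ord, lexicon$number)
  list(task = task,
       numbers = lexicon$word[idx],
       phones = unlist(strsplit(lexicon$phones[idx], " ", fixed = TRUE),
                       use.names = FALSE))
}

.labelCategoryTable <- function(config) {
  labs <- config$labels
  data.frame(label = unlist(labs, use.names = FALSE),
             category = rep(names(labs), lengths(labs)),
             stringsAsFactors = FALSE)
}

.resolveCategory <- function(labels, catTable, lexiconWords) {
  out <- data.frame(label = labels, category = NA_character_,
                    stringsAsFactors = FALSE)
  marked <- grepl("#", labels, fixed = TRUE)
  if (any(marked)) {
    parts <- strsplit(labels[marked], "#", fixed = TRUE)
    out$label[marked] <- vapply(parts, `[`, character(1), 1L)
    out$category[marked] <- vapply(parts, `[`, character(1), 2L)
    bad <- !out$category[marked] %in% EVENT_CATEGORIES
    if (any(bad))
      stop("unknown category marker(s): ",
           paste(unique(out$category[marked][bad]), collapse = ", "),
           call. = FALSE)
  }
  unres <- is.na(out$category)
  hit <- match(out$label[unres], catTable$label)
  out$category[unres][!is.na(hit)] <- catTable$category[hit[!is.na(hit)]]
  unres <- is.na(out$category)
  out$category[unres][out$label[unres] %in% lexiconWords] <- "number"
  if (anyNA(out$category))
    stop("unmapped annotation label(s): ",
         paste(unique(out$label[is.na(out$category)]), collapse = ", "),
         call. = FALSE)
  out
}

#' Read a counting-task annotation from a Praat TextGrid
#'
#' Parses the word and phone interval tiers, drops empty-label intervals, and
#' assigns each event its category. Also derives silences at the configured
#' minimum-silence threshold.
#'
#' @param path TextGrid file (long or short dialect, UTF-8 or UTF-16).
#' @param task `"forward"` or `"backward"`.
#' @param config an [annotationConfig()] list.
#' @param lexicon a [numberLexicon()] table used to recognise number labels.
#' @return an [AnnotatedTask-class] with silences derived.
#' @export
readTextGrid <- function(path, task = c("forward", "backward"),
                         config = annotationConfig(),
                         lexicon = numberLexicon()) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tiers <- .parseTextGrid(path)
  byName <- setNames(tiers, vapply(tiers, `[[`, character(1), "name"))
  catTable <- .labelCategoryTable(config)

  tierEvents <- function(tierName, phoneTier = FALSE) {
    tier <- byName[[tierName]]
    if (is.null(tier)) return(NULL)
    ivs <- Filter(function(iv) nzchar(trimws(iv$text)), tier$intervals)
    if (!length(ivs)) return(.emptyEvents())
    ev <- data.frame(
      label = vapply(ivs, function(iv) trimws(iv$text), character(1)),
      start = vapply(ivs, `[[`, numeric(1), "xmin"),
      end = vapply(ivs, `[[`, numeric(1), "xmax"),
      stringsAsFactors = FALSE)
    if (phoneTier) {
      res <- .resolveCategory(ev$label, catTable, lexiconWords = ev$label)
    } else {
      res <- .resolveCategory(ev$label, catTable, lexiconWords = lexicon$word)
    }
    ev$label <- res$label
    ev$category <- res$category
    ev[, c("label", "category", "start", "end")]
  }

  words <- tierEvents(config$tiers$words)
  if (is.null(words))
    stop("word tier '", config$tiers$words, "' not found in ", path,
         call. = FALSE)
  phones <- tierEvents(config$tiers$phones, phoneTier = TRUE)
  if (is.null(phones)) phones <- .emptyEvents()
  if (nrow(words) == 0)
    warning("empty word tier in ", path, call. = FALSE)
  at <- AnnotatedTask(task, words, phones, audioRef = NA_character_)
  validObject(at)
  deriveSilences(at, minSilence = config$silence$min_silence)
}

#' Write an AnnotatedTask as a long-format TextGrid
#'
#' Non-number categories are encoded as a `label#category` suffix so a
#' write/read round trip reproduces events and categories exactly.
#'
#' @param task an [AnnotatedTask-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTextGrid <- function(task, path) {
  encLabel <- function(ev)
    ifelse(ev$category == "number", ev$label,
           paste0(ev$label, "#", ev$category))
  span <- function(ev) if (nrow(ev)) c(0, max(ev$end)) else c(0, 1)
  tmax <- max(span(task@events)[2], span(task@phoneEvents)[2])

  tierBlock <- function(idx, name, ev) {
    lab <- encLabel(ev)
    # fill gaps with empty intervals so the grid tiles [0, tmax]
    edges <- sort(unique(c(0, ev$start, ev$end, tmax)))
    out <- c(sprintf("    item [%d]:", idx),
             "        class = \"IntervalTier\"",
             sprintf("        name = \"%s\"", name),
             "        xmin = 0",
             sprintf("        xmax = %.10g", tmax))
    ivs <- list()
    for (i in seq_len(length(edges) - 1)) {
      a <- edges[i]; b <- edges[i + 1]
      hit <- which(abs(ev$start - a) < 1e-12 & abs(ev$end - b) < 1e-12)
      txt <- if (length(hit)) lab[hit[1]] else ""
      ivs[[length(ivs) + 1L]] <- sprintf(
        "        intervals [%d]:\n            xmin = %.10g\n            xmax = %.10g\n            text = \"%s\"",
        length(ivs) + 1L, a, b, gsub('"', '""', txt))
    }
    c(out, sprintf("        intervals: size = %d", length(ivs)),
      unlist(ivs))
  }
  lines <- c("File type = \"ooTextFile\"",
             "Object class = \"TextGrid\"",
             "",
             "xmin = 0",
             sprintf("xmax = %.10g", tmax),
             "tiers? <exists>",
             "size = 2",
             "item []:",
             tierBlock(1, "words", task@events),
             tierBlock(2, "phones", task@phoneEvents))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Derive inter-event silences
#'
#' Silences are the gaps between consecutive word-tier events whose length is
#' at least `minSilence` seconds; shorter gaps are ignored, and the regions
#' before the first and after the last event are never silences.
#'
#' @param task an [AnnotatedTask-class].
#' @param minSilence minimum gap duration in seconds (default 0.1 s, the
#'   conventional pause threshold).
#' @return the task with its `silences` slot populated.
#' @export
deriveSilences <- function(task, minSilence = 0.1) {
  ev <- task@events
  sil <- data.frame(start = numeric(), end = numeric())
  if (nrow(ev) > 1) {
    gapStart <- ev$end[-nrow(ev)]
    gapEnd <- ev$start[-1]
    len <- gapEnd - gapStart
    keep <- len >= minSilence - 1e-12 & len > 0
    sil <- data.frame(start = gapStart[keep], end = gapEnd[keep])
  }
  rownames(sil) <- NULL
  task@silences <- sil
  task
}

#' Task duration
#'
#' Offset of the last word-tier event minus the onset of the first, in
#' seconds. Robust to recording lead-in/lead-out, which the protocol does not
#' control.
#'
#' @param task an [AnnotatedTask-class] with at least one word event.
#' @return duration in seconds.
#' @export
taskDuration <- function(task) {
  ev <- task@events
  if (nrow(ev) == 0)
    stop("task has no word events; duration undefined", call. = FALSE)
  ev$end[nrow(ev)] - ev$start[1]
}
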
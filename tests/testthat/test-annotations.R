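test_that("TextGrid round trip preserves events, categories and times", {
  task <- makeTask("forward",
                   labels = c("1", "2", "euh", "3"),
                   categories = c("number", "pronunciation_error_block",
                                  "filled_pause", "number"),
                   starts = c(0, 0.6, 1.2, 1.8),
                   ends = c(0.4, 1.0, 1.5, 2.3),
                   phoneLabels = c("P01", "P02"),
                   phoneStarts = c(0, 0.2), phoneEnds = c(0.2, 0.4))
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeTextGrid(task, path)
  back <- readTextGrid(path, "forward")
  expect_equal(back@events$label, task@events$label)
  expect_equal(back@events$category, task@events$category)
  expect_equal(back@events$start, task@events$start, tolerance = 1e-6)
  expect_equal(back@events$end, task@events$end, tolerance = 1e-6)
  expect_equal(back@phoneEvents$label, task@phoneEvents$label)
})

test_that("reader maps labels through the category table and lexicon", {
  lex <- numberLexicon("french")
  ev <- data.frame(label = c("un", "deux", "euh"),
                   category = "number",
                   start = c(0, 0.6, 1.2), end = c(0.4, 1.0, 1.5),
                   stringsAsFactors = FALSE)
  task <- AnnotatedTask("forward", ev)
  path <- withr::local_tempfile(fileext = ".TextGrid")
  # write without markers: every label must resolve via config or lexicon
  task@events$category <- "number"
  writeTextGrid(task, path)
  got <- readTextGrid(path, "forward", lexicon = lex)
  expect_equal(got@events$category,
               c("number", "number", "filled_pause"))
})

test_that("short-dialect and UTF-16 TextGrids parse identically", {
  task <- makeCleanTask(n = 4)
  longPath <- withr::local_tempfile(fileext = ".TextGrid")
  writeTextGrid(task, longPath)
  ref <- readTextGrid(longPath, "forward")

  # short dialect built from the same events
  shortPath <- withr::local_tempfile(fileext = ".TextGrid")
  ev <- task@events
  lines <- c("File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "",
             "0", sprintf("%.10g", max(ev$end)), "<exists>", "1",
             "\"IntervalTier\"", "\"words\"", "0",
             sprintf("%.10g", max(ev$end)), as.character(nrow(ev)),
             unlist(lapply(seq_len(nrow(ev)), function(i)
               c(sprintf("%.10g", ev$start[i]), sprintf("%.10g", ev$end[i]),
                 sprintf("\"%s\"", ev$label[i])))))
  writeLines(lines, shortPath)
  gotShort <- readTextGrid(shortPath, "forward")
  expect_equal(gotShort@events$label, ref@events$label)
  expect_equal(gotShort@events$start, ref@events$start, tolerance = 1e-6)

  # UTF-16LE with BOM
  u16 <- withr::local_tempfile(fileext = ".TextGrid")
  con <- file(u16, open = "wb")
  writeBin(as.raw(c(0xFF, 0xFE)), con)
  writeBin(iconv(paste(readLines(longPath), collapse = "\n"), "UTF-8",
                 "UTF-16LE", toRaw = TRUE)[[1]], con)
  close(con)
  gotU16 <- readTextGrid(u16, "forward")
  expect_equal(gotU16@events$label, ref@events$label)
})

test_that("malformed input is rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c("not a textgrid"), p)
  expect_error(readTextGrid(p, "forward"), "parse error at line 1")

  # overlapping word intervals violate the tier invariant
  expect_error(
    makeTask("forward", labels = c("1", "2"),
             categories = c("number", "number"),
             starts = c(0, 0.35), ends = c(0.4, 0.8)),
    "overlapping")

  # unknown unmapped label
  task <- makeCleanTask(n = 2)
  task@events$label[1] <- "banana"
  p2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeTextGrid(task, p2)
  expect_error(readTextGrid(p2, "forward"), "banana")
})

test_that("an empty word tier yields zero events and a warning", {
  lines <- c("File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "",
             "xmin = 0", "xmax = 2", "tiers? <exists>", "size = 1",
             "item []:", "    item [1]:",
             "        class = \"IntervalTier\"", "        name = \"words\"",
             "        xmin = 0", "        xmax = 2",
             "        intervals: size = 1", "        intervals [1]:",
             "            xmin = 0", "            xmax = 2",
             "            text = \"\"")
  p <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(lines, p)
  expect_warning(task <- readTextGrid(p, "forward"), "empty word tier")
  expect_equal(nrow(task@events), 0)
})

test_that("silence derivation follows the threshold rule", {
  t1 <- makeTask("forward", labels = c("1", "2"), categories = rep("number", 2),
                 starts = c(0, 0.9), ends = c(0.5, 1.4))
  expect_equal(t1@silences, data.frame(start = 0.5, end = 0.9))

  # contiguous events: no silence
  t2 <- makeTask("forward", labels = c("1", "2"), categories = rep("number", 2),
                 starts = c(0, 0.5), ends = c(0.5, 1.0))
  expect_equal(nrow(t2@silences), 0)

  # sub-threshold gap ignored
  t3 <- makeTask("forward", labels = c("1", "2"), categories = rep("number", 2),
                 starts = c(0, 0.54), ends = c(0.5, 1.0))
  expect_equal(nrow(t3@silences), 0)
})

test_that("silences + events + sub-threshold gaps partition the task span", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    durs <- runif(n, 0.1, 0.6)
    gaps <- runif(n - 1, 0, 0.4)
    starts <- cumsum(c(0, durs[-n] + gaps))
    task <- makeTask("forward", labels = as.character(seq_len(n)),
                     categories = rep("number", n),
                     starts = starts, ends = starts + durs)
    silSum <- sum(task@silences$end - task@silences$start)
    evSum <- sum(durs)
    subGaps <- sum(gaps[gaps < 0.1])
    expect_equal(silSum + evSum + subGaps, taskDuration(task),
                 tolerance = 1e-9)
    # silence count non-increasing in the threshold
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4),
                     function(m) nrow(deriveSilences(task, m)@silences),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("task duration is first onset to last offset", {
  t1 <- makeTask("forward", labels = c("1", "2"), categories = rep("number", 2),
                 starts = c(0.2, 10.0), ends = c(0.7, 10.9))
  expect_equal(taskDuration(t1), 10.7)
  t2 <- makeTask("forward", labels = "1", categories = "number",
                 starts = 1.0, ends = 1.5)
  expect_equal(taskDuration(t2), 0.5)
  empty <- AnnotatedTask("forward")
  expect_error(taskDuration(empty), "no word events")
})
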
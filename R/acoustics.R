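# Frame-level acoustics: F0 by normalised autocorrelation with parabolic peak
# interpolation, RMS intensity in dB re full scale, and a simplified
# modulation-energy intelligibility index (low- vs high-rate envelope energy,
# averaged over acoustic bands). The index is a fully specified, deterministic
# stand-in for normed speech-to-reverberation modulation-energy metrics, and
# is documented as such.

#' Read a mono waveform from a PCM WAV file
#'
#' Supports 16- and 24-bit PCM at any sample rate; multi-channel input is
#' averaged to mono. Samples are rescaled to \code{[-1, 1]}.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric) and `rate` (Hz).
#' @export
readWaveMono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sampleRate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bitsPerSample = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing fmt/data chunk")
  if (!fmt$audioFormat %in% c(1L)) stop("only PCM WAV supported")
  bytes <- fmt$bitsPerSample / 8
  if (!bytes %in% c(2, 3)) stop("only 16/24-bit PCM supported")
  n <- length(data) %/% bytes
  if (bytes == 2) {
    x <- readBin(data, "integer", n, size = 2, signed = TRUE,
                 endian = "little") / 2^15
  } else {
    m <- matrix(as.integer(data[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  }
  if (fmt$nChannels > 1) {
    nf <- length(x) %/% fmt$nChannels
    x <- rowMeans(matrix(x[seq_len(nf * fmt$nChannels)],
                         ncol = fmt$nChannels, byrow = TRUE))
  }
  list(samples = x, rate = fmt$sampleRate)
}

.frameIndex <- function(n, rate, frameStep, window) {
  step <- max(1L, round(frameStep * rate))
  win <- max(2L, round(window * rate))
  starts <- seq(1L, n - win + 1L, by = step)
  list(starts = starts, win = win,
       centers = (starts + win / 2 - 0.5) / rate)
}

#' Fundamental-frequency contour by autocorrelation
#'
#' Per-frame normalised autocorrelation with parabolic interpolation of the
#' peak inside the \code{[fmin, fmax]} lag range. Frames whose peak
#' autocorrelation (periodicity confidence) falls below `confidence`, or whose
#' energy is negligible, are marked unvoiced. Voiced values are clipped to
#' \code{[fmin, fmax]}.
#'
#' @param samples mono waveform in \code{[-1, 1]}.
#' @param rate sample rate (Hz), at least 8 kHz.
#' @param fmin,fmax pitch search range (defaults 60-400 Hz).
#' @param frameStep frame step in seconds (default 10 ms).
#' @param confidence voicing threshold on the normalised peak (default 0.45).
#' @return a [Contour-class] in Hz.
#' @export
f0Contour <- function(samples, rate, fmin = 60, fmax = 400,
                      frameStep = 0.01, confidence = 0.45) {
  if (length(samples) == 0) stop("empty audio", call. = FALSE)
  stopifnot(rate >= 8000, fmin >= 50, fmin < fmax, fmax <= 600)
  window <- max(0.04, 2.5 / fmin)
  fr <- .frameIndex(length(samples), rate, frameStep, window)
  lagMin <- max(2L, floor(rate / fmax))
  lagMax <- min(fr$win - 2L, ceiling(rate / fmin))
  vals <- rep(NA_real_, length(fr$starts))
  voiced <- rep(FALSE, length(fr$starts))
  for (i in seq_along(fr$starts)) {
    seg <- samples[fr$starts[i]:(fr$starts[i] + fr$win - 1L)]
    seg <- seg - mean(seg)
    r0 <- sum(seg * seg)
    if (r0 < 1e-10) next
    ac <- stats::acf(seg, lag.max = lagMax, plot = FALSE,
                     demean = FALSE, type = "covariance")$acf[, 1, 1]
    r <- ac / ac[1]
    idx <- (lagMin + 1L):(lagMax + 1L)   # r[lag + 1]
    pk <- idx[which.max(r[idx])]
    conf <- r[pk]
    if (!is.finite(conf) || conf < confidence) next
    lag <- pk - 1L
    if (pk > 2 && pk < length(r)) {      # parabolic refinement
      a <- r[pk - 1]; b <- r[pk]; cc <- r[pk + 1]
      den <- a - 2 * b + cc
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (a - cc) / den
    }
    f <- rate / lag
    vals[i] <- min(fmax, max(fmin, f))
    voiced[i] <- TRUE
  }
  Contour(fr$centers, vals, voiced, frameStep, unit = "Hz")
}

#' Intensity contour in dB re full scale
#'
#' Per-frame RMS energy expressed as \code{20 log10(rms)} relative to a
#' full-scale amplitude of 1. Frames of exact silence receive the floor value
#' (-120 dB).
#'
#' @param samples mono waveform.
#' @param rate sample rate (Hz).
#' @param frameStep frame step in seconds (default 10 ms).
#' @param floorDb floor value for all-zero frames.
#' @return a [Contour-class] in dB.
#' @export
intensityContour <- function(samples, rate, frameStep = 0.01,
                             floorDb = -120) {
  if (length(samples) == 0) stop("empty audio", call. = FALSE)
  fr <- .frameIndex(length(samples), rate, frameStep, window = 0.04)
  vals <- vapply(seq_along(fr$starts), function(i) {
    seg <- samples[fr$starts[i]:(fr$starts[i] + fr$win - 1L)]
    rms <- sqrt(mean(seg^2))
    if (rms <= 10^(floorDb / 20)) floorDb else 20 * log10(rms)
  }, numeric(1))
  Contour(fr$centers, vals, rep(TRUE, length(vals)), frameStep, unit = "dB")
}

#' Simplified modulation-energy intelligibility index
#'
#' Ratio of envelope-modulation energy at speech-like rates (3-20 Hz) to
#' fast-modulation energy (20-80 Hz), averaged over four acoustic bands.
#' Clean, syllabically modulated speech concentrates envelope energy in the
#' low modulation band and scores high; noise-like or reverberant segments
#' score low. Deterministic for fixed input.
#'
#' @param samples mono waveform segment, at least 0.2 s long.
#' @param rate sample rate (Hz).
#' @return non-negative score, or `NA` (with a warning) for too-short input.
#' @export
intelligibilityIndex <- function(samples, rate) {
  if (length(samples) / rate < 0.2) {
    warning("segment shorter than 0.2 s; intelligibility undefined",
            call. = FALSE)
    return(NA_real_)
  }
  nyq <- rate / 2
  edges <- list(c(150, 550), c(550, 1550), c(1550, 3550),
                c(3550, min(7000, 0.95 * nyq)))
  envRate <- 400
  dec <- max(1L, floor(rate / envRate))
  fsEnv <- rate / dec
  ratios <- vapply(edges, function(e) {
    if (e[2] <= e[1]) return(NA_real_)
    bp <- signal::butter(3, e / nyq, type = "pass")
    band <- signal::filtfilt(bp, samples)
    env <- abs(band)
    lp <- signal::butter(3, min(0.99, 100 / nyq), type = "low")
    env <- signal::filtfilt(lp, env)
    env <- env[seq(1, length(env), by = dec)]
    env <- env - mean(env)
    nfft <- 2^ceiling(log2(max(length(env), fsEnv)))  # >= 1 s => <= 1 Hz bins
    sp <- Mod(fft(c(env, rep(0, nfft - length(env)))))^2
    freqs <- (seq_len(nfft) - 1) * fsEnv / nfft
    lowE <- sum(sp[freqs >= 3 & freqs < 20])
    highE <- sum(sp[freqs >= 20 & freqs < 80])
    lowE / (highE + 1e-12)
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}

#' Compute all acoustic contours for one annotated task
#'
#' Convenience wrapper: F0 and intensity contours over the recording plus the
#' per-word-event intelligibility scores (events shorter than 0.2 s are
#' skipped). Phonatory features only consume frames inside word events, so
#' computing contours over the whole recording is safe.
#'
#' @param task an [AnnotatedTask-class].
#' @param samples,rate mono waveform and its sample rate.
#' @param ... passed to [f0Contour()].
#' @return a [TaskContours-class].
#' @export
computeTaskContours <- function(task, samples, rate, ...) {
  f0 <- f0Contour(samples, rate, ...)
  int <- intensityContour(samples, rate)
  ev <- task@events
  intel <- numeric(0)
  if (nrow(ev)) {
    keep <- (ev$end - ev$start) >= 0.2
    intel <- vapply(which(keep), function(i) {
      a <- max(1L, floor(ev$start[i] * rate) + 1L)
      b <- min(length(samples), ceiling(ev$end[i] * rate))
      intelligibilityIndex(samples[a:b], rate)
    }, numeric(1))
  }
  TaskContours(f0, int, intel)
}
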
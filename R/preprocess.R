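#' Design a Butterworth band-pass filter
#'
#' Maximally-flat IIR band-pass whose magnitude response is -3 dB (1/sqrt(2))
#' at both cut-off frequencies. The default (8-30 Hz, order 5) isolates the
#' mu and beta rhythms that carry the event-related desynchronization used
#' by motor-imagery classifiers, while removing DC drift and line noise.
#'
#' @param low_hz lower cut-off in Hz.
#' @param high_hz upper cut-off in Hz.
#' @param order filter order (per band edge); default 5.
#' @param fs sampling rate in Hz.
#' @return A list of class \code{"FilterSpec"}: \code{b}, \code{a}
#'   (transfer-function coefficients), plus the design parameters.
#' @examples
#' spec <- designBandpass(8, 30, 5, 100)
#' @export
designBandpass <- function(low_hz, high_hz, order = 5L, fs) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop(sprintf(
      "need 0 < low (%g) < high (%g) < fs/2 (%g)", low_hz, high_hz, fs / 2))
  if (order < 1L) stop("order must be >= 1")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  structure(list(b = bf$b, a = bf$a, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), fs = fs),
            class = "FilterSpec")
}

#' Magnitude response of a FilterSpec
#'
#' @param spec a \code{FilterSpec}.
#' @param freqs_hz frequencies at which to evaluate, in Hz.
#' @return Numeric vector of magnitude gains.
#' @export
filterResponse <- function(spec, freqs_hz) {
  w <- 2 * pi * freqs_hz / spec$fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz)
    sum(spec$b * zz^(-(seq_along(spec$b) - 1))), complex(1))
  den <- vapply(z, function(zz)
    sum(spec$a * zz^(-(seq_along(spec$a) - 1))), complex(1))
  Mod(num / den)
}

#' Apply a band-pass filter channel-wise
#'
#' Filters every channel independently. The default is a causal single-pass
#' application, so the realized order equals the design order; set
#' \code{zeroPhase = TRUE} for forward-backward (zero-phase) filtering,
#' which squares the magnitude response.
#'
#' @param x an \linkS4class{EpochSet} or \linkS4class{ContinuousRecording}.
#' @param spec a \code{FilterSpec} from \code{\link{designBandpass}}; its
#'   \code{fs} must match the data.
#' @param zeroPhase logical; forward-backward filtering if TRUE.
#' @return The same class as \code{x}, filtered.
#' @export
applyFilter <- function(x, spec, zeroPhase = FALSE) {
  filt1 <- function(v) {
    if (zeroPhase)
      as.numeric(signal::filtfilt(signal::Arma(b = spec$b, a = spec$a), v))
    else
      as.numeric(signal::filter(spec$b, spec$a, v))
  }
  if (is(x, "ContinuousRecording")) {
    if (!isTRUE(all.equal(x@samplingRate, spec$fs)))
      stop(sprintf("filter designed for fs = %g but data has fs = %g",
                   spec$fs, x@samplingRate))
    x@data <- t(apply(x@data, 1L, filt1))
    return(x)
  }
  if (is(x, "EpochSet")) {
    if (!isTRUE(all.equal(x@samplingRate, spec$fs)))
      stop(sprintf("filter designed for fs = %g but data has fs = %g",
                   spec$fs, x@samplingRate))
    d <- x@data
    for (tr in seq_len(dim(d)[1L]))
      for (ch in seq_len(dim(d)[2L]))
        d[tr, ch, ] <- filt1(d[tr, ch, ])
    x@data <- d
    return(x)
  }
  stop("applyFilter expects an EpochSet or ContinuousRecording")
}

#' Cut marker-locked epochs from a continuous recording
#'
#' For every marker at (1-based) sample m, extracts the half-open window
#' [m + round(start*fs), m + round(end*fs)) and copies the marker's label.
#' With the conventional window (0, 2.5) s at 100 Hz each epoch is 250
#' samples.
#'
#' @param rec a \linkS4class{ContinuousRecording} with markers attached.
#' @param window_s numeric length-2: window start and end in seconds,
#'   relative to the marker.
#' @param classNames optional class names for the resulting EpochSet.
#' @return An \linkS4class{EpochSet} with one epoch per marker.
#' @export
extractEpochs <- function(rec, window_s = c(0, 2.5), classNames = NULL) {
  if (length(window_s) != 2L || window_s[2] <= window_s[1])
    stop("window_s must be (start, end) with end > start")
  fs <- rec@samplingRate
  off0 <- round(window_s[1] * fs)
  nS <- round((window_s[2] - window_s[1]) * fs)
  if (nS < 1L) stop("window too short: zero samples at this sampling rate")
  mk <- rec@markers
  if (!nrow(mk)) stop("recording has no markers")
  first <- mk$sample_index + off0
  last <- first + nS - 1L
  bad <- which(first < 1L | last > ncol(rec@data))
  if (length(bad))
    stop(sprintf(
      "epoch window exceeds recording bounds at marker %d (sample %d)",
      bad[1], mk$sample_index[bad[1]]))
  out <- array(0, c(nrow(mk), nrow(rec@data), nS))
  for (i in seq_len(nrow(mk)))
    out[i, , ] <- rec@data[, first[i]:last[i]]
  EpochSet(out, mk$label, rec@channelNames, fs, classNames = classNames)
}
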
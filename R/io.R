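CONTAINER_SCHEMA_VERSION <- "1.0"

#' Write an EpochSet to the on-disk epoch container
#'
#' Self-describing single-file JSON container: dimensions, sampling rate,
#' channel and class names, labels, schema version, and the trial data
#' flattened in (trial, channel, sample) order with sample varying
#' fastest. Numbers are written with 17 significant digits, so the
#' round trip through \code{\link{readEpochs}} is bit-exact for doubles.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param path output file path; written atomically (temp file + rename).
#' @return invisible \code{path}.
#' @export
writeEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  # flatten with sample fastest: aperm puts dims as (sample, channel, trial)
  flat <- as.vector(aperm(epochs@data, c(3L, 2L, 1L)))
  obj <- list(
    schema_version = CONTAINER_SCHEMA_VERSION,
    fs = epochs@samplingRate,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    channel_names = epochs@channelNames,
    class_names = epochs@classNames,
    labels = epochs@labels,
    data = flat)
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE),
             tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an EpochSet from the epoch container
#'
#' Validates the schema on read: every required field must be present and
#' the dimensions must be consistent, otherwise an error names the
#' offending field.
#'
#' @param path container file written by \code{\link{writeEpochs}}.
#' @return An \linkS4class{EpochSet}.
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path)
  need <- c("schema_version", "fs", "n_trials", "n_channels", "n_samples",
            "channel_names", "labels", "data")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("epoch container schema error: missing field(s) ",
         paste(miss, collapse = ", "))
  d <- c(obj$n_trials, obj$n_channels, obj$n_samples)
  if (length(obj$data) != prod(d))
    stop(sprintf(
      "epoch container dimension mismatch: data has %d values, header %s",
      length(obj$data), paste(d, collapse = "x")))
  if (length(obj$labels) != d[1L])
    stop("epoch container schema error: labels length != n_trials")
  arr <- aperm(array(obj$data, dim = c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  EpochSet(arr, obj$labels, obj$channel_names, obj$fs,
           classNames = obj$class_names %||% NULL)
}

#' Read a continuous EDF recording with an optional marker table
#'
#' Minimal reader for EDF (European Data Format) files: parses the fixed
#' 256-byte header plus per-signal headers, decodes the 16-bit samples
#' with the per-signal physical scaling, and requires one common sampling
#' rate across channels. Annotation channels are not supported; markers
#' come from a CSV sidecar with columns \code{sample_index} (1-based) and
#' \code{label}.
#'
#' @param path EDF file.
#' @param markerCsv optional CSV path with the marker table.
#' @return A \linkS4class{ContinuousRecording}.
#' @export
readContinuousEDF <- function(path, markerCsv = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdStr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rdNum <- function(n) as.numeric(rdStr(n))
  rdStr(8)                               # version
  rdStr(80); rdStr(80)                   # patient / recording id
  rdStr(8); rdStr(8)                     # start date / time
  headerBytes <- rdNum(8)
  rdStr(44)                              # reserved
  nRecords <- rdNum(8)
  recDur <- rdNum(8)
  nSig <- as.integer(rdNum(4))
  labels <- vapply(seq_len(nSig), function(i) rdStr(16), "")
  for (i in seq_len(nSig)) rdStr(80)     # transducer
  for (i in seq_len(nSig)) rdStr(8)      # physical dimension
  physMin <- vapply(seq_len(nSig), function(i) rdNum(8), 0)
  physMax <- vapply(seq_len(nSig), function(i) rdNum(8), 0)
  digMin <- vapply(seq_len(nSig), function(i) rdNum(8), 0)
  digMax <- vapply(seq_len(nSig), function(i) rdNum(8), 0)
  for (i in seq_len(nSig)) rdStr(80)     # prefiltering
  nsPerRec <- vapply(seq_len(nSig), function(i) as.integer(rdNum(8)), 0L)
  for (i in seq_len(nSig)) rdStr(32)     # reserved
  stopifnot(headerBytes == 256 + 256 * nSig)
  if (length(unique(nsPerRec)) != 1L)
    stop("EDF signals have inconsistent sampling rates; ",
         "a common rate is required")
  fs <- nsPerRec[1L] / recDur
  gain <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, nSig, nRecords * nsPerRec[1L])
  for (r in seq_len(nRecords)) {
    for (s in seq_len(nSig)) {
      raw <- readBin(con, "integer", n = nsPerRec[s], size = 2L,
                     signed = TRUE, endian = "little")
      cols <- (r - 1L) * nsPerRec[s] + seq_len(nsPerRec[s])
      data[s, cols] <- physMin[s] + gain[s] * (raw - digMin[s])
    }
  }
  markers <- data.frame(sample_index = integer(0), label = integer(0))
  if (!is.null(markerCsv)) markers <- readMarkerCsv(markerCsv, ncol(data))
  new("ContinuousRecording", data = data, samplingRate = fs,
      channelNames = labels, markers = markers)
}

#' Read a marker table CSV
#'
#' @param path CSV with columns \code{sample_index} (1-based), \code{label}.
#' @param nSamplesTotal optional recording length for bounds checking.
#' @return data.frame with integer columns.
#' @export
readMarkerCsv <- function(path, nSamplesTotal = NULL) {
  mk <- utils::read.csv(path)
  if (!all(c("sample_index", "label") %in% names(mk)))
    stop("marker CSV needs columns sample_index and label")
  mk$sample_index <- as.integer(mk$sample_index)
  mk$label <- as.integer(mk$label)
  if (!is.null(nSamplesTotal) &&
      (any(mk$sample_index < 1L) || any(mk$sample_index > nSamplesTotal)))
    stop("marker sample_index outside recording bounds")
  mk[, c("sample_index", "label")]
}

#' Write provenance of an AugmentedSet as CSV
#'
#' Sidecar table with one row per trial: method, right/left source subject
#' and trial, label, and the original-trial flag.
#'
#' @param aug an \linkS4class{AugmentedSet}.
#' @param path output CSV path.
#' @return invisible \code{path}.
#' @export
writeProvenanceCsv <- function(aug, path) {
  stopifnot(is(aug, "AugmentedSet"))
  prov <- cbind(trial = seq_len(nTrials(aug)), provenance(aug))
  utils::write.csv(prov, path, row.names = FALSE)
  invisible(path)
}

# Minimal EDF writer (internal; used for fixtures and exports).
# Writes one data record per second, int16 with symmetric physical range.
.writeEDF <- function(data, fs, channelNames, path) {
  nSig <- nrow(data)
  stopifnot(length(channelNames) == nSig)
  if (ncol(data) %% fs != 0)
    stop("recording length must be a whole number of seconds")
  nRecords <- ncol(data) / fs
  physMax <- max(1, ceiling(max(abs(data))))
  digMax <- 32767
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(pad(x, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + 256 * nSig, 8); wr("", 44)
  wr(nRecords, 8); wr(1, 8); wr(nSig, 4)
  for (ch in channelNames) wr(ch, 16)
  for (i in seq_len(nSig)) wr("", 80)
  for (i in seq_len(nSig)) wr("uV", 8)
  for (i in seq_len(nSig)) wr(-physMax, 8)
  for (i in seq_len(nSig)) wr(physMax, 8)
  for (i in seq_len(nSig)) wr(-digMax, 8)
  for (i in seq_len(nSig)) wr(digMax, 8)
  for (i in seq_len(nSig)) wr("", 80)
  for (i in seq_len(nSig)) wr(fs, 8)
  for (i in seq_len(nSig)) wr("", 32)
  for (r in seq_len(nRecords)) {
    cols <- (r - 1L) * fs + seq_len(fs)
    for (s in seq_len(nSig)) {
      dig <- as.integer(round(data[s, cols] / physMax * digMax))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
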
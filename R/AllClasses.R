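#' @import methods
NULL

#' EpochSet: epoched multichannel EEG
#'
#' Container for a set of fixed-length EEG trials with per-trial class
#' labels. The data array is trials x channels x samples; channel order is
#' canonical for every operation in the package (hemisphere splitting,
#' spatial filtering, augmentation provenance all refer to it).
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot labels integer vector of class ids (1-based into \code{classNames}).
#' @slot channelNames character vector of 10-20 labels, one per channel.
#' @slot samplingRate sampling rate in Hz.
#' @slot classNames character vector naming the classes.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    labels = "integer",
    channelNames = "character",
    samplingRate = "numeric",
    classNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array (trials x channels x samples)")
  if (length(object@labels) != d[1L])
    return(sprintf("labels length (%d) != number of trials (%d)",
                   length(object@labels), d[1L]))
  if (length(object@channelNames) != d[2L])
    return(sprintf("channelNames length (%d) != number of channels (%d)",
                   length(object@channelNames), d[2L]))
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (d[1L] > 0L &&
      (anyNA(object@labels) || any(object@labels < 1L) ||
       any(object@labels > length(object@classNames))))
    return("labels must index into classNames")
  TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples numeric array.
#' @param labels integer or factor class labels, one per trial.
#' @param channelNames channel labels in array order.
#' @param samplingRate sampling rate in Hz.
#' @param classNames class names; defaults to \code{"class<k>"} over the
#'   label range.
#' @return An \linkS4class{EpochSet}.
#' @examples
#' es <- EpochSet(array(rnorm(2 * 2 * 10), c(2, 2, 10)),
#'                labels = c(1, 2), channelNames = c("C3", "C4"),
#'                samplingRate = 100)
#' nTrials(es)
#' @export
EpochSet <- function(data, labels, channelNames, samplingRate,
                     classNames = NULL) {
  labels <- as.integer(labels)
  if (is.null(classNames)) {
    nc <- if (length(labels)) max(labels) else 0L
    classNames <- paste0("class", seq_len(nc))
  }
  new("EpochSet", data = data, labels = labels,
      channelNames = as.character(channelNames),
      samplingRate = as.numeric(samplingRate),
      classNames = as.character(classNames))
}

#' HemisphereSplit: left/right partition of a montage
#'
#' Ordered index sets assigning every channel of a montage to the left or
#' right hemisphere. Lateral channels are assigned by the 10-20 parity
#' convention; midline ('z') channels are alternated (see
#' \code{\link{hemisphereSplit}}).
#'
#' @slot left integer indices (montage order) of left-side channels.
#' @slot right integer indices (montage order) of right-side channels.
#' @slot channelNames the montage the indices refer to.
#' @export
setClass("HemisphereSplit",
  representation(
    left = "integer",
    right = "integer",
    channelNames = "character"
  )
)

setValidity("HemisphereSplit", function(object) {
  C <- length(object@channelNames)
  all_idx <- sort(c(object@left, object@right))
  if (!identical(all_idx, seq_len(C)))
    return("left and right indices must partition 1..C")
  if (is.unsorted(object@left) || is.unsorted(object@right))
    return("index sets must preserve montage order")
  TRUE
})

#' HemiEpochs: one hemisphere's half-trials
#'
#' The half-samples produced by \code{\link{halveEpochs}}: every trial of an
#' \linkS4class{EpochSet} restricted to one hemisphere's channels, with the
#' source trial index and label retained so recombination can be audited.
#'
#' @slot data trials x channels' x samples array (one side's channels).
#' @slot side "left" or "right".
#' @slot sourceTrial integer vector of originating trial indices.
#' @slot labels class ids copied from the source trials.
#' @export
setClass("HemiEpochs",
  representation(
    data = "array",
    side = "character",
    sourceTrial = "integer",
    labels = "integer"
  )
)

setValidity("HemiEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be 3-d")
  if (!object@side %in% c("left", "right"))
    return("side must be 'left' or 'right'")
  if (length(object@sourceTrial) != d[1L] || length(object@labels) != d[1L])
    return("sourceTrial/labels length must equal trial count")
  TRUE
})

#' AugmentedSet: an EpochSet with per-trial provenance
#'
#' Extends \linkS4class{EpochSet} with a provenance table recording, for
#' every trial, which augmenter produced it and which original trials (and
#' subjects) supplied its right- and left-hemisphere blocks.
#'
#' @slot provenance data.frame with columns \code{method},
#'   \code{right_subject}, \code{right_trial}, \code{left_subject},
#'   \code{left_trial}, \code{label}, \code{is_original}.
#' @export
setClass("AugmentedSet",
  contains = "EpochSet",
  representation(provenance = "data.frame")
)

setValidity("AugmentedSet", function(object) {
  if (nrow(object@provenance) != dim(object@data)[1L])
    return("provenance rows must equal trial count")
  need <- c("method", "right_subject", "right_trial",
            "left_subject", "left_trial", "label", "is_original")
  if (!all(need %in% names(object@provenance)))
    return(paste("provenance must have columns:",
                 paste(need, collapse = ", ")))
  TRUE
})

#' SpatialFilterBank: CSP filters with eigenvalues
#'
#' 2k spatial filters from the generalized eigendecomposition of a pair of
#' class covariance matrices: the first k columns maximize the class-1 to
#' class-2 variance ratio, the last k the swapped ratio. Each filter w is
#' normalized so that w' C w = 1 in its own denominator covariance.
#'
#' @slot filters channels x 2k matrix; columns are filters.
#' @slot eigenvalues generalized eigenvalue of each filter in its own
#'   (possibly swapped) problem, descending within each class block.
#' @slot classOfFilter integer vector (1 or 2) attributing each column.
#' @slot k number of filters per class.
#' @slot channelNames montage the filters apply to.
#' @export
setClass("SpatialFilterBank",
  representation(
    filters = "matrix",
    eigenvalues = "numeric",
    classOfFilter = "integer",
    k = "integer",
    channelNames = "character"
  )
)

setValidity("SpatialFilterBank", function(object) {
  k <- object@k
  if (ncol(object@filters) != 2L * k)
    return("filters must have 2k columns")
  if (length(object@eigenvalues) != 2L * k)
    return("eigenvalues must have length 2k")
  if (!identical(object@classOfFilter, rep(1:2, each = k)))
    return("first k columns must be class 1, last k class 2")
  TRUE
})

#' ContinuousRecording: unsegmented multichannel EEG
#'
#' @slot data channels x samples matrix.
#' @slot samplingRate Hz.
#' @slot channelNames one label per row.
#' @slot markers data.frame with columns \code{sample_index} (1-based) and
#'   \code{label}.
#' @export
setClass("ContinuousRecording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    markers = "data.frame"
  )
)

setValidity("ContinuousRecording", function(object) {
  if (nrow(object@data) != length(object@channelNames))
    return("channelNames length must equal row count of data")
  if (nrow(object@markers) > 0) {
    if (!all(c("sample_index", "label") %in% names(object@markers)))
      return("markers need columns sample_index and label")
    si <- object@markers$sample_index
    if (any(si < 1L) || any(si > ncol(object@data)))
      return("marker sample indices must lie within the recording")
  }
  TRUE
})

#' ExperimentResult: accuracy records from an evaluation run
#'
#' @slot records data.frame with one row per (subject, size, repeat):
#'   columns \code{subject}, \code{schema}, \code{augmenter}, \code{size},
#'   \code{rep}, \code{accuracy}, \code{seed}.
#' @slot config the ExperimentConfig list the run used.
#' @export
setClass("ExperimentResult",
  representation(records = "data.frame", config = "list")
)

setValidity("ExperimentResult", function(object) {
  need <- c("subject", "schema", "augmenter", "size", "rep", "accuracy")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  acc <- object@records$accuracy
  if (length(acc) && (any(acc < 0) || any(acc > 1)))
    return("accuracy must lie in [0, 1]")
  TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d trials x %d channels x %d samples @ %g Hz\n",
              class(object), d[1], d[2], d[3], object@samplingRate))
  if (d[1] > 0) {
    tab <- table(factor(object@classNames[object@labels],
                        levels = object@classNames))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  cat("  channels:", paste(utils::head(object@channelNames, 8),
                           collapse = " "),
      if (d[2] > 8) "..." else "", "\n")
})

setMethod("show", "AugmentedSet", function(object) {
  callNextMethod()
  m <- table(object@provenance$method)
  cat("  provenance:", paste(sprintf("%s=%d", names(m), m),
                             collapse = ", "), "\n")
})

setMethod("show", "HemisphereSplit", function(object) {
  cat(sprintf("HemisphereSplit over %d channels\n",
              length(object@channelNames)))
  cat("  left :", paste(object@channelNames[object@left], collapse = " "),
      "\n")
  cat("  right:", paste(object@channelNames[object@right], collapse = " "),
      "\n")
})

setMethod("show", "SpatialFilterBank", function(object) {
  cat(sprintf("SpatialFilterBank: %d channels, k = %d per class\n",
              nrow(object@filters), object@k))
  cat("  eigenvalues:",
      paste(sprintf("%.3g", object@eigenvalues), collapse = " "), "\n")
})

setMethod("show", "ExperimentResult", function(object) {
  r <- object@records
  cat(sprintf("ExperimentResult: %d records (%s-schema, augmenter = %s)\n",
              nrow(r), object@config$schema %||% "?",
              object@config$augmenter %||% "?"))
  if (nrow(r)) {
    cat(sprintf("  subjects: %d, sizes: %s, repeats: %d\n",
                length(unique(r$subject)),
                paste(sort(unique(r$size)), collapse = ","),
                max(r$rep)))
    cat(sprintf("  mean accuracy: %.3f\n", mean(r$accuracy)))
  }
})
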
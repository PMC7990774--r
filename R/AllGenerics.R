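#' @name accessors
#' @title Accessors for barEEG classes
#' @description Slot accessors: number of trials/channels/samples, the data
#'   array, labels, channel names, sampling rate, provenance table, CSP
#'   filter matrix and eigenvalues, and evaluation records.
#' @param x an object of the relevant class.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("cspFilters", function(x) standardGeneric("cspFilters"))
#' @rdname accessors
#' @export
setGeneric("cspEigenvalues", function(x) standardGeneric("cspEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("resultRecords", function(x) standardGeneric("resultRecords"))

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2L])
#' @rdname accessors
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3L])
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname accessors
setMethod("classNames", "EpochSet", function(x) x@classNames)
#' @rdname accessors
setMethod("provenance", "AugmentedSet", function(x) x@provenance)
#' @rdname accessors
setMethod("cspFilters", "SpatialFilterBank", function(x) x@filters)
#' @rdname accessors
setMethod("cspEigenvalues", "SpatialFilterBank", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("resultRecords", "ExperimentResult", function(x) x@records)
#' @rdname accessors
setMethod("nChannels", "ContinuousRecording",
          function(x) nrow(x@data))
#' @rdname accessors
setMethod("nSamples", "ContinuousRecording",
          function(x) ncol(x@data))
#' @rdname accessors
setMethod("channelNames", "ContinuousRecording",
          function(x) x@channelNames)
#' @rdname accessors
setMethod("samplingRate", "ContinuousRecording",
          function(x) x@samplingRate)

#' Subset an EpochSet by trial
#'
#' @param x an EpochSet (or AugmentedSet; provenance rows follow).
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @return An object of the same class with the selected trials.
#' @export
setMethod("[", signature("EpochSet", "ANY", "missing"),
  function(x, i, j, ..., drop = FALSE) {
    x@data <- x@data[i, , , drop = FALSE]
    x@labels <- x@labels[i]
    x
  })

#' @rdname sub-EpochSet-ANY-missing-method
#' @export
setMethod("[", signature("AugmentedSet", "ANY", "missing"),
  function(x, i, j, ..., drop = FALSE) {
    x@data <- x@data[i, , , drop = FALSE]
    x@labels <- x@labels[i]
    x@provenance <- x@provenance[i, , drop = FALSE]
    rownames(x@provenance) <- NULL
    x
  })
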
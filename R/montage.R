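#' Classify a 10-20 channel label by hemisphere
#'
#' Applies the standard 10-20 parity convention: labels ending in an odd
#' digit sit over the left hemisphere, even digits over the right, and a
#' terminal 'z' (case-insensitive) marks a midline electrode. Labels with
#' embedded digits (e.g. "AF7") are classified by the terminal digit.
#'
#' @param label character vector of channel names.
#' @return Character vector with elements "left", "right" or "midline".
#' @examples
#' channelSide(c("C3", "C4", "FCz", "AF7"))
#' @export
channelSide <- function(label) {
  if (!length(label) || any(!nzchar(label)))
    stop("channel labels must be non-empty strings")
  last <- substr(label, nchar(label), nchar(label))
  out <- rep(NA_character_, length(label))
  out[last %in% c("z", "Z")] <- "midline"
  dig <- grepl("[0-9]", last)
  digit <- suppressWarnings(as.integer(last[dig]))
  out[dig] <- ifelse(digit %% 2L == 1L, "left", "right")
  if (anyNA(out))
    stop("unparseable channel label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "),
         " (no terminal digit or 'z')")
  out
}

#' Build the left/right hemisphere partition of a montage
#'
#' Lateral channels are assigned by label parity. Midline ('z') channels,
#' taken in montage order, are alternated between the hemispheres starting
#' with the left: the 1st, 3rd, 5th... midline electrode joins the left
#' set, the 2nd, 4th... the right set. An explicit override map can replace
#' the automatic midline assignment (e.g. to reproduce a published split).
#'
#' @param channelNames ordered character vector of 10-20 labels, or an
#'   \linkS4class{EpochSet} whose montage is used.
#' @param midlineOverride optional named character vector mapping midline
#'   labels to "left"/"right"; overridden labels bypass the alternation.
#' @return A \linkS4class{HemisphereSplit}.
#' @examples
#' hemisphereSplit(c("C3", "C4", "Fz", "FCz", "Cz", "CPz", "Pz"))
#' @export
hemisphereSplit <- function(channelNames, midlineOverride = NULL) {
  if (is(channelNames, "EpochSet"))
    channelNames <- channelNames@channelNames
  if (!length(channelNames)) stop("empty montage")
  side <- channelSide(channelNames)
  mid <- which(side == "midline")
  if (length(mid)) {
    # alternate in montage order, starting LEFT
    side[mid] <- rep(c("left", "right"), length.out = length(mid))
    if (!is.null(midlineOverride)) {
      bad <- setdiff(names(midlineOverride), channelNames[mid])
      if (length(bad))
        stop("midlineOverride names not midline channels of this montage: ",
             paste(bad, collapse = ", "))
      if (!all(midlineOverride %in% c("left", "right")))
        stop("midlineOverride values must be 'left' or 'right'")
      hit <- match(names(midlineOverride), channelNames)
      side[hit] <- unname(midlineOverride)
    }
  }
  new("HemisphereSplit",
      left = which(side == "left"),
      right = which(side == "right"),
      channelNames = channelNames)
}

#' Split an EpochSet into hemispheric half-trials
#'
#' Restricts every trial to the left (resp. right) hemisphere's channels,
#' producing two \linkS4class{HemiEpochs} objects whose rows are exact
#' copies of the source rows in split order, and which remember their
#' source trial index and label.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param split a \linkS4class{HemisphereSplit} over the same montage.
#' @return \code{list(left = HemiEpochs, right = HemiEpochs)}.
#' @export
halveEpochs <- function(epochs, split) {
  .checkSplit(epochs, split)
  mk <- function(idx, side) {
    new("HemiEpochs",
        data = epochs@data[, idx, , drop = FALSE],
        side = side,
        sourceTrial = seq_len(nTrials(epochs)),
        labels = epochs@labels)
  }
  list(left = mk(split@left, "left"), right = mk(split@right, "right"))
}

.checkSplit <- function(epochs, split) {
  C <- nChannels(epochs)
  if (length(split@left) + length(split@right) != C)
    stop(sprintf("split covers %d channels but epochs have %d",
                 length(split@left) + length(split@right), C))
  if (!identical(split@channelNames, epochs@channelNames))
    stop("split was built for a different montage than these epochs")
  invisible(TRUE)
}

#' Recombine hemispheric half-trials into full trials
#'
#' Pairs the i-th trial of \code{right} with the i-th trial of \code{left}
#' and scatters their rows back to the original montage positions given by
#' \code{split}: the output is in canonical montage channel order, not a
#' stacked [right; left] block. When both halves carry labels the labels
#' must agree pairwise.
#'
#' @param right \linkS4class{HemiEpochs} with side "right".
#' @param left \linkS4class{HemiEpochs} with side "left".
#' @param split the \linkS4class{HemisphereSplit} the halves came from.
#' @param samplingRate sampling rate for the result (Hz).
#' @param classNames optional class names for the result.
#' @return An \linkS4class{EpochSet} with one trial per input pair.
#' @export
recombineHalves <- function(right, left, split, samplingRate,
                            classNames = NULL) {
  if (right@side != "right" || left@side != "left")
    stop("arguments must be a right-side and a left-side HemiEpochs ",
         "(got '", right@side, "' and '", left@side, "')")
  if (dim(right@data)[1L] != dim(left@data)[1L])
    stop("halves must contain the same number of trials")
  if (dim(right@data)[3L] != dim(left@data)[3L])
    stop("sample counts differ between halves")
  if (dim(right@data)[2L] != length(split@right) ||
      dim(left@data)[2L] != length(split@left))
    stop("half channel counts do not match the split")
  if (any(right@labels != left@labels))
    stop("label mismatch between paired halves; recombination is ",
         "defined within a class only")
  n <- dim(right@data)[1L]
  C <- length(split@channelNames)
  S <- dim(right@data)[3L]
  out <- array(0, c(n, C, S))
  out[, split@right, ] <- right@data
  out[, split@left, ] <- left@data
  EpochSet(out, right@labels, split@channelNames, samplingRate,
           classNames = classNames)
}
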
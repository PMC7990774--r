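.provRow <- function(n) {
  data.frame(method = character(n), right_subject = integer(n),
             right_trial = integer(n), left_subject = integer(n),
             left_trial = integer(n), label = integer(n),
             is_original = logical(n))
}

# Enumerate per-class ordered (right, left) index pairs for BAR.
# rows/cols are data.frames with columns subject, trial, label (global
# row ids refer into the stacked half arrays). Order: (class, right, left).
.barPairs <- function(rightTab, leftTab, classes, maxPerClass, seed) {
  pieces <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    ri <- which(rightTab$label == cl)
    li <- which(leftTab$label == cl)
    if (!length(ri) || !length(li))
      stop(sprintf("class %s has no trials; BAR needs >= 1 trial per class",
                   cl))
    grid <- expand.grid(left = li, right = ri,
                        KEEP.OUT.ATTRS = FALSE)[, c("right", "left")]
    # expand.grid varies its first factor fastest; column order above puts
    # pairs in (right-major, left-minor) order per the determinism rule
    grid <- grid[order(grid$right, grid$left), , drop = FALSE]
    ident <- rightTab$subject[grid$right] == leftTab$subject[grid$left] &
      rightTab$trial[grid$right] == leftTab$trial[grid$left]
    if (!is.null(maxPerClass) && nrow(grid) > maxPerClass) {
      nId <- sum(ident)
      if (maxPerClass < nId)
        stop(sprintf(
          "max_pairs_per_class (%d) below identity-pair count (%d)",
          maxPerClass, nId))
      others <- which(!ident)
      keepN <- maxPerClass - nId
      keep <- sort(c(which(ident),
                     withSeed(deriveSeed(seed, ci), {
                       others[sample.int(length(others), keepN)]
                     })))
      grid <- grid[keep, , drop = FALSE]
      ident <- ident[keep]
    }
    cbind(grid, class = cl, is_identity = ident)
  })
  do.call(rbind, pieces)
}

# Assemble an AugmentedSet from half-trial stacks and a pair table.
.assembleBar <- function(pairs, rightData, leftData, rightTab, leftTab,
                         split, samplingRate, classNames, method) {
  n <- nrow(pairs)
  C <- length(split@channelNames)
  S <- dim(rightData)[3L]
  out <- array(0, c(n, C, S))
  out[, split@right, ] <- rightData[pairs$right, , , drop = FALSE]
  out[, split@left, ] <- leftData[pairs$left, , , drop = FALSE]
  prov <- data.frame(
    method = method,
    right_subject = rightTab$subject[pairs$right],
    right_trial = rightTab$trial[pairs$right],
    left_subject = leftTab$subject[pairs$left],
    left_trial = leftTab$trial[pairs$left],
    label = pairs$class,
    is_original = pairs$is_identity)
  new("AugmentedSet",
      data = out, labels = as.integer(pairs$class),
      channelNames = split@channelNames,
      samplingRate = samplingRate, classNames = classNames,
      provenance = prov)
}

#' Brain-area recombination within one subject
#'
#' Splits every trial into left- and right-hemisphere halves and forms, per
#' class, the full cartesian product of right halves x left halves. Identity
#' pairs (same source trial on both sides) are included, so the augmented
#' set contains the originals and has exactly n_c^2 trials per class. An
#' optional cap subsamples the product (seeded, without replacement) while
#' always retaining all identity pairs.
#'
#' @param epochs an \linkS4class{EpochSet} (one subject's training trials).
#' @param split a \linkS4class{HemisphereSplit} for the montage.
#' @param maxPairsPerClass optional integer cap per class.
#' @param seed seed used only when the cap triggers subsampling.
#' @param subject subject id recorded in provenance (default 1).
#' @return An \linkS4class{AugmentedSet}.
#' @examples
#' es <- simulateSubject(synthParams(nTrialsPerClass = 5, seed = 1))$epochs
#' aug <- barIntra(es, hemisphereSplit(es))
#' nTrials(aug)  # 2 * 5^2
#' @export
barIntra <- function(epochs, split, maxPairsPerClass = NULL, seed = 1L,
                     subject = 1L) {
  .checkSplit(epochs, split)
  halves <- halveEpochs(epochs, split)
  tab <- data.frame(subject = as.integer(subject),
                    trial = seq_len(nTrials(epochs)),
                    label = epochs@labels)
  classes <- seq_along(epochs@classNames)
  pairs <- .barPairs(tab, tab, classes, maxPairsPerClass, seed)
  .assembleBar(pairs, halves$right@data, halves$left@data, tab, tab,
               split, epochs@samplingRate, epochs@classNames, "bar")
}

#' Brain-area recombination across subjects
#'
#' Builds the cross-subject augmented set for a target subject s: the union
#' over all ordered source-subject pairs (i, j) with i != s and j != s
#' (i = j allowed unless \code{allowSameSource = FALSE}) of the per-class
#' products {right halves of subject i} x {left halves of subject j}. No
#' half originates from the target subject, making the result a leakage-free
#' pre-training set.
#'
#' @param subjectSets list of \linkS4class{EpochSet}s, one per subject,
#'   sharing montage and sampling rate.
#' @param excludedSubject index of the target subject s.
#' @param split a \linkS4class{HemisphereSplit}.
#' @param maxPairsPerClass optional per-class cap (seeded subsample keeping
#'   identity pairs).
#' @param seed seed for the cap.
#' @param allowSameSource if FALSE, drop i = j source pairs.
#' @return An \linkS4class{AugmentedSet} with full provenance.
#' @export
barMulti <- function(subjectSets, excludedSubject, split,
                     maxPairsPerClass = NULL, seed = 1L,
                     allowSameSource = TRUE) {
  nS <- length(subjectSets)
  if (nS < 2L) stop("barMulti needs >= 2 subjects")
  if (excludedSubject < 1L || excludedSubject > nS)
    stop("excludedSubject out of range")
  sources <- setdiff(seq_len(nS), excludedSubject)
  for (s in sources) .checkSplit(subjectSets[[s]], split)
  ref <- subjectSets[[sources[1]]]

  halveOne <- function(s) halveEpochs(subjectSets[[s]], split)
  hv <- lapply(sources, halveOne)
  stack <- function(side) {
    arrs <- lapply(hv, function(h) h[[side]]@data)
    do.call(abind3, arrs)
  }
  tabOne <- function(s)
    data.frame(subject = s, trial = seq_len(nTrials(subjectSets[[s]])),
               label = subjectSets[[s]]@labels)
  tab <- do.call(rbind, lapply(sources, tabOne))
  rightData <- stack("right")
  leftData <- stack("left")

  classes <- seq_along(ref@classNames)
  pairs <- .barPairs(tab, tab, classes, NULL, seed)
  if (!allowSameSource)
    pairs <- pairs[tab$subject[pairs$right] != tab$subject[pairs$left], ,
                   drop = FALSE]
  if (!is.null(maxPairsPerClass)) {
    keep <- unlist(lapply(classes, function(cl) {
      rows <- which(pairs$class == cl)
      if (length(rows) <= maxPairsPerClass) return(rows)
      ident <- rows[pairs$is_identity[rows]]
      others <- setdiff(rows, ident)
      if (maxPairsPerClass < length(ident))
        stop(sprintf(
          "max_pairs_per_class (%d) below identity-pair count (%d)",
          maxPairsPerClass, length(ident)))
      sort(c(ident, withSeed(deriveSeed(seed, match(cl, classes)), {
        others[sample.int(length(others), maxPairsPerClass - length(ident))]
      })))
    }))
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  .assembleBar(pairs, rightData, leftData, tab, tab, split,
               ref@samplingRate, ref@classNames, "bar_multi")
}

# rbind for 3-d arrays along the first (trial) axis
abind3 <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1L], 0L)
  d <- dim(arrs[[1L]])
  out <- array(0, c(sum(ns), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    if (n) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' Time-axis flipping augmentation
#'
#' Returns the originals plus a time-reversed copy of every trial (exactly
#' doubling the set). Reversal preserves each trial's power spectrum
#' magnitude but destroys its temporal ordering.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param subject subject id recorded in provenance.
#' @return An \linkS4class{AugmentedSet} of size 2n.
#' @export
flipTime <- function(epochs, subject = 1L) {
  n <- nTrials(epochs)
  if (!n) stop("cannot flip an empty EpochSet")
  S <- nSamples(epochs)
  flipped <- epochs@data[, , rev(seq_len(S)), drop = FALSE]
  out <- abind3(epochs@data, flipped)
  prov <- .provRow(2L * n)
  prov$method <- rep(c("original", "flip"), each = n)
  prov$right_subject <- prov$left_subject <- rep(as.integer(subject), 2L * n)
  prov$right_trial <- prov$left_trial <- rep(seq_len(n), 2L)
  prov$label <- rep(epochs@labels, 2L)
  prov$is_original <- rep(c(TRUE, FALSE), each = n)
  new("AugmentedSet",
      data = out, labels = rep(epochs@labels, 2L),
      channelNames = epochs@channelNames,
      samplingRate = epochs@samplingRate, classNames = epochs@classNames,
      provenance = prov)
}

#' SNR-controlled additive Gaussian noise augmentation
#'
#' Generates artificial trials by adding white Gaussian noise to recorded
#' trials, rescaled per trial so that the linear power ratio
#' var(trial) / var(noise) equals \code{snr} exactly (default 5). Two
#' expansion-ratio versions: \code{"v1"} adds one noisy copy per original
#' (total 2n, the flipping ratio); \code{"v2"} draws source trials
#' uniformly with replacement until the total reaches \code{targetSize},
#' typically set to the size of the matching BAR product.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param snr target linear power ratio (> 0). Interpreted in dB when
#'   \code{snrInDb = TRUE}.
#' @param mode "v1" or "v2".
#' @param targetSize total output size for v2 (originals included).
#' @param seed integer seed; same seed gives bit-identical output.
#' @param snrInDb treat \code{snr} as decibels.
#' @param subject subject id recorded in provenance.
#' @return An \linkS4class{AugmentedSet}.
#' @export
addNoise <- function(epochs, snr = 5, mode = c("v1", "v2"),
                     targetSize = NULL, seed = 1L, snrInDb = FALSE,
                     subject = 1L) {
  mode <- match.arg(mode)
  if (snrInDb) snr <- 10^(snr / 10)
  if (snr <= 0) stop("snr must be positive")
  n <- nTrials(epochs)
  if (!n) stop("cannot augment an empty EpochSet")
  if (mode == "v1") {
    src <- seq_len(n)
  } else {
    if (is.null(targetSize))
      stop("v2 requires targetSize (e.g. the matching BAR output size)")
    if (targetSize < n)
      stop(sprintf("targetSize (%d) must be >= n originals (%d)",
                   targetSize, n))
    src <- withSeed(deriveSeed(seed, 2L), {
      sample.int(n, targetSize - n, replace = TRUE)
    })
  }
  S <- nSamples(epochs); C <- nChannels(epochs)
  gen <- array(0, c(length(src), C, S))
  noiseSeed <- deriveSeed(seed, 1L)
  withSeed(noiseSeed, {
    for (k in seq_along(src)) {
      x <- epochs@data[src[k], , ]
      noise <- matrix(stats::rnorm(C * S), C, S)
      scale <- sqrt(stats::var(as.vector(x)) /
                      (snr * stats::var(as.vector(noise))))
      gen[k, , ] <- x + scale * noise
    }
  })
  out <- abind3(epochs@data, gen)
  m <- length(src)
  prov <- .provRow(n + m)
  prov$method <- c(rep("original", n), rep(paste0("noise_", mode), m))
  prov$right_subject <- prov$left_subject <- as.integer(subject)
  prov$right_trial <- prov$left_trial <- c(seq_len(n), src)
  prov$label <- c(epochs@labels, epochs@labels[src])
  prov$is_original <- c(rep(TRUE, n), rep(FALSE, m))
  new("AugmentedSet",
      data = out, labels = c(epochs@labels, epochs@labels[src]),
      channelNames = epochs@channelNames,
      samplingRate = epochs@samplingRate, classNames = epochs@classNames,
      provenance = prov)
}
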
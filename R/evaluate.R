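#' Configuration for an evaluation run
#'
#' @param schema "IS" (intra-subject) or "AS" (adaptive: cross-subject
#'   pre-training then target fine-tuning).
#' @param sizes training-set sizes to sweep (default 10 to 100 by 10).
#' @param nRepeats repeats per (subject, size) cell (default 10); each
#'   repeat redraws the training subset and re-augments it.
#' @param augmenter one of "none", "bar", "flip", "noise_v1", "noise_v2".
#' @param snr linear SNR for the noise augmenter.
#' @param classifier an object honoring the classifier contract
#'   (default \code{\link{cspSvmClassifier}()}).
#' @param seed master seed; every cell derives its own seed from it.
#' @return A list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(schema = c("IS", "AS"),
                             sizes = seq(10L, 100L, by = 10L),
                             nRepeats = 10L,
                             augmenter = c("none", "bar", "flip",
                                           "noise_v1", "noise_v2"),
                             snr = 5,
                             classifier = cspSvmClassifier(),
                             seed = 1L) {
  schema <- match.arg(schema)
  augmenter <- match.arg(augmenter)
  if (any(sizes < 1L)) stop("sizes must be positive")
  structure(list(schema = schema, sizes = as.integer(sizes),
                 nRepeats = as.integer(nRepeats), augmenter = augmenter,
                 snr = snr, classifier = classifier,
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Split a subject's epochs into training pool and held-out test set
#'
#' Class-balanced, seeded, without replacement: \code{nTrain} trials go to
#' the pool, the rest to the test set. The pool and test set are disjoint
#' by construction; augmentation only ever sees the pool.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param nTrain pool size (balanced across classes).
#' @param seed integer seed.
#' @return \code{list(train = EpochSet, test = EpochSet,
#'   trainIdx, testIdx)} (indices into \code{epochs}).
#' @export
splitTrainTest <- function(epochs, nTrain = 100L, seed = 1L) {
  idx <- balancedSample(epochs@labels, nTrain, seed)
  test <- setdiff(seq_len(nTrials(epochs)), idx)
  list(train = epochs[idx], test = epochs[test],
       trainIdx = idx, testIdx = test)
}

# Build the augmented training set for one subject's subset.
# Returns the AugmentedSet (or plain EpochSet for "none") whose provenance
# trial ids refer to positions in `subset`.
.augmentIS <- function(subset, split, augmenter, snr, seed, subject = 1L) {
  n <- nTrials(subset)
  switch(augmenter,
    none = subset,
    bar = barIntra(subset, split, seed = seed, subject = subject),
    flip = flipTime(subset, subject = subject),
    noise_v1 = addNoise(subset, snr = snr, mode = "v1", seed = seed,
                        subject = subject),
    noise_v2 = {
      counts <- table(subset@labels)
      target <- sum(counts^2)            # matching BAR product size
      addNoise(subset, snr = snr, mode = "v2", targetSize = target,
               seed = seed, subject = subject)
    },
    stop("unknown augmenter: ", augmenter))
}

#' Intra-subject evaluation sweep
#'
#' For every (subject, training-set size, repeat): draw a class-balanced
#' training subset from the subject's pool (seeded), augment it with the
#' configured method, fit the classifier from scratch, and score on the
#' subject's untouched test set. Augmentation never sees test trials; the
#' per-record seed is derived from the master seed and the cell counters,
#' so a rerun with the same configuration is bit-identical.
#'
#' @param subjects list with one element per subject:
#'   \code{list(train = EpochSet, test = EpochSet)} as produced by
#'   \code{\link{splitTrainTest}}.
#' @param cfg an \code{ExperimentConfig} with \code{schema = "IS"}.
#' @return An \linkS4class{ExperimentResult}; its records also carry the
#'   sampled pool indices (as a comma-joined string) for leakage audits.
#' @export
runIS <- function(subjects, cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  split <- hemisphereSplit(subjects[[1]]$train@channelNames)
  rows <- list()
  for (s in seq_along(subjects)) {
    pool <- subjects[[s]]$train
    test <- subjects[[s]]$test
    for (size in cfg$sizes) {
      for (r in seq_len(cfg$nRepeats)) {
        seed <- deriveSeed(cfg$seed, 1L, s, size, r)
        idx <- balancedSample(pool@labels, size, seed)
        subset <- pool[idx]
        train <- .augmentIS(subset, split, cfg$augmenter, cfg$snr,
                            deriveSeed(seed, 2L), subject = s)
        state <- fitClassifier(cfg$classifier, train, seed = seed)
        pred <- predictClassifier(cfg$classifier, state, test)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, schema = "IS", augmenter = cfg$augmenter,
          size = size, rep = r,
          accuracy = mean(pred == test@labels), seed = seed,
          train_pool_idx = paste(idx, collapse = ","))
      }
    }
  }
  new("ExperimentResult", records = do.call(rbind, rows),
      config = unclass(cfg))
}

# Stage-1 cross-subject augmented pool for target s. sourceSubsets is the
# list (indexed by subject) of per-source sampled EpochSets (NULL at s).
.augmentAS <- function(sourceSubsets, s, split, augmenter, snr, seed) {
  sources <- which(!vapply(sourceSubsets, is.null, TRUE))
  mixed <- Reduce(bindEpochs, sourceSubsets[sources])
  switch(augmenter,
    none = mixed,
    bar = barMulti(sourceSubsets, excludedSubject = s, split = split,
                   seed = seed),
    flip = flipTime(mixed, subject = 0L),
    noise_v1 = addNoise(mixed, snr = snr, mode = "v1", seed = seed,
                        subject = 0L),
    noise_v2 = {
      counts <- table(mixed@labels)
      target <- sum(counts^2)            # matching BAR-multi product size
      addNoise(mixed, snr = snr, mode = "v2", targetSize = target,
               seed = seed, subject = 0L)
    },
    stop("unknown augmenter: ", augmenter))
}

#' Adaptive-subject evaluation sweep
#'
#' Two-stage schema. Stage 1 (pre-training): from every non-target subject
#' draw \code{size} pool trials, build the cross-subject augmented set
#' (BAR uses the multi-subject recombination; flip/noise act on the mixed
#' source pool, noise v2 resampling with replacement up to the matching
#' BAR size), and fit the classifier. Stage 2 (adaptive training):
#' warm-start from the stage-1 state and fit on the target's own augmented
#' subset, exactly as in the intra-subject schema. Scores on the target's
#' held-out test set. No stage-1 trial originates from the target subject.
#'
#' @param subjects list per subject of \code{list(train, test)}.
#' @param cfg an \code{ExperimentConfig} with \code{schema = "AS"}.
#' @param skipPretrain if TRUE, skip stage 1 (the run then degenerates to
#'   the intra-subject schema; for testing).
#' @return An \linkS4class{ExperimentResult}.
#' @export
runAS <- function(subjects, cfg, skipPretrain = FALSE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  if (length(subjects) < 2L) stop("AS-schema needs >= 2 subjects")
  if (!skipPretrain && !supportsWarmStart(cfg$classifier))
    stop("classifier does not support warm start; the adaptive schema ",
         "requires fitClassifier(state = <stage-1 state>) to continue ",
         "training")
  split <- hemisphereSplit(subjects[[1]]$train@channelNames)
  rows <- list()
  for (s in seq_along(subjects)) {
    test <- subjects[[s]]$test
    for (size in cfg$sizes) {
      for (r in seq_len(cfg$nRepeats)) {
        seed <- deriveSeed(cfg$seed, 1L, s, size, r)
        state0 <- NULL
        if (!skipPretrain) {
          sourceSubsets <- vector("list", length(subjects))
          for (j in seq_along(subjects)) {
            if (j == s) next
            jIdx <- balancedSample(subjects[[j]]$train@labels, size,
                                   deriveSeed(seed, 3L, j))
            sourceSubsets[[j]] <- subjects[[j]]$train[jIdx]
          }
          pre <- .augmentAS(sourceSubsets, s, split, cfg$augmenter,
                            cfg$snr, deriveSeed(seed, 4L))
          state0 <- fitClassifier(cfg$classifier, pre, seed = seed)
        }
        idx <- balancedSample(subjects[[s]]$train@labels, size, seed)
        subset <- subjects[[s]]$train[idx]
        train <- .augmentIS(subset, split, cfg$augmenter, cfg$snr,
                            deriveSeed(seed, 2L), subject = s)
        state <- fitClassifier(cfg$classifier, train, state = state0,
                               seed = seed)
        pred <- predictClassifier(cfg$classifier, state, test)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, schema = "AS", augmenter = cfg$augmenter,
          size = size, rep = r,
          accuracy = mean(pred == test@labels), seed = seed,
          train_pool_idx = paste(idx, collapse = ","))
      }
    }
  }
  new("ExperimentResult", records = do.call(rbind, rows),
      config = unclass(cfg))
}

#' Per-subject mean accuracies of a run
#'
#' The averaging convention of the sweep: a subject's final accuracy is
#' the mean over all sizes and repeats.
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @return Named numeric vector, one mean per subject.
#' @export
subjectMeans <- function(result) {
  r <- resultRecords(result)
  tapply(r$accuracy, r$subject, mean)
}

#' Paired-sample t-test
#'
#' Classical paired t on the per-subject differences a - b: t equals
#' mean(d) / (sd(d) / sqrt(n)), with a two-sided p from the t distribution
#' on n - 1 degrees of freedom. Zero variance of the differences makes the
#' statistic undefined and raises an error rather than returning a silent
#' p-value.
#'
#' @param a,b equal-length numeric vectors paired by subject.
#' @return \code{list(t, df, p, meanDiff)}.
#' @examples
#' pairedTTest(c(2, 4, 6), c(1, 2, 3))  # t = 2*sqrt(3)
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need >= 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop("zero variance of paired differences: t statistic undefined")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L),
       meanDiff = mean(d))
}

#' Audit an evaluation run for train/test leakage
#'
#' Structural check that no record's sampled training-pool indices
#' intersect the held-out test indices. Returns invisibly TRUE or stops
#' with the offending record.
#'
#' @param result an \linkS4class{ExperimentResult} from \code{runIS} or
#'   \code{runAS}.
#' @param subjects the subject list the run used (for the test indices).
#' @return invisible TRUE when clean.
#' @export
auditLeakage <- function(result, subjects) {
  r <- resultRecords(result)
  for (i in seq_len(nrow(r))) {
    s <- r$subject[i]
    used <- as.integer(strsplit(r$train_pool_idx[i], ",")[[1]])
    if (any(used < 1L) || any(used > nTrials(subjects[[s]]$train)))
      stop(sprintf("record %d references trials outside subject %d's pool",
                   i, s))
    # map pool positions back to the subject's original trial ids and
    # verify none of them sits in the held-out test set
    trainIdx <- subjects[[s]]$trainIdx
    testIdx <- subjects[[s]]$testIdx
    if (!is.null(trainIdx) && !is.null(testIdx) &&
        length(intersect(trainIdx[used], testIdx)))
      stop(sprintf("leakage: record %d (subject %d) trained on test trials",
                   i, s))
  }
  invisible(TRUE)
}
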
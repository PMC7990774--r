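`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used everywhere randomness is nested
#' (per-subject generation, per-(subject, size, repeat) subsampling):
#' the master seed and a sequence of small integer counters are folded
#' through a multiplicative hash, keeping the result a valid 32-bit seed.
#' Runs are reproducible from the master seed and the counters alone.
#'
#' @param master master seed (integer).
#' @param ... integer counters identifying the consumer.
#' @return A single integer in [0, 2^31 - 2].
#' @examples
#' deriveSeed(42, 1, 3) != deriveSeed(42, 3, 1)
#' @export
deriveSeed <- function(master, ...) {
  parts <- c(as.numeric(master), vapply(list(...), as.numeric, 0))
  h <- 0
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  for (p in parts) {
    h <- (h * 48271 + (p %% m) + 1) %% m
  }
  as.integer(h)
}

#' Evaluate a function with a local RNG seed
#'
#' Sets the seed, runs \code{expr}, and restores the caller's RNG state so
#' seeded internals do not disturb user-level randomness.
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stratified balanced sample of trial indices
#'
#' Draws \code{size} trial indices without replacement, split as evenly as
#' possible across classes (exactly even when \code{size} is divisible by
#' the number of classes). Errors when any class cannot supply its share.
#'
#' @param labels integer class labels.
#' @param size total number of trials to draw.
#' @param seed integer seed.
#' @return Sorted integer vector of trial indices.
#' @export
balancedSample <- function(labels, size, seed) {
  classes <- sort(unique(labels))
  nc <- length(classes)
  base <- size %/% nc
  extra <- size %% nc
  per <- rep(base, nc) + c(rep(1L, extra), rep(0L, nc - extra))
  idx <- withSeed(seed, {
    unlist(lapply(seq_along(classes), function(ci) {
      pool <- which(labels == classes[ci])
      if (length(pool) < per[ci])
        stop(sprintf(
          "class %s has %d trials, cannot supply %d for a balanced subset",
          classes[ci], length(pool), per[ci]))
      if (per[ci] == 0L) integer(0)
      else pool[sample.int(length(pool), per[ci])]
    }))
  })
  sort(idx)
}

# Bind two EpochSets (same montage/fs) trial-wise.
bindEpochs <- function(a, b) {
  stopifnot(identical(a@channelNames, b@channelNames),
            isTRUE(all.equal(a@samplingRate, b@samplingRate)))
  d <- array(0, c(nTrials(a) + nTrials(b), nChannels(a), nSamples(a)))
  if (nTrials(a)) d[seq_len(nTrials(a)), , ] <- a@data
  if (nTrials(b)) d[nTrials(a) + seq_len(nTrials(b)), , ] <- b@data
  EpochSet(d, c(a@labels, b@labels), a@channelNames, a@samplingRate,
           classNames = a@classNames)
}
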
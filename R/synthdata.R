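#' Parameters for the synthetic motor-imagery generator
#'
#' Describes two-class trials with hemisphere-lateralized event-related
#' desynchronization (ERD): each trial is broadband background noise plus
#' one band-limited oscillatory source per hemisphere, projected onto that
#' hemisphere's sensorimotor channels. Class 1 ("left-hand imagery")
#' attenuates the RIGHT-hemisphere source's amplitude by a factor
#' (1 - erdDepth); class 2 attenuates the left one. The two hemispheric
#' sources are drawn independently given the class — the idealization
#' under which hemispheric recombination is distribution-exact.
#'
#' @param channelNames montage; default 14 10-20 labels including C3/C4
#'   and two midline electrodes.
#' @param fs sampling rate (Hz), default 100.
#' @param durationS trial length in seconds, default 2.5.
#' @param nTrialsPerClass trials per class, default 100.
#' @param erdDepth fractional ERD amplitude attenuation in [0, 1),
#'   default 0.6.
#' @param oscillationBand mu-rhythm band (Hz), default c(8, 12).
#' @param backgroundNoiseSd broadband sensor-noise SD, default 1.
#' @param sourceScale oscillatory source SD before projection, default 2.
#' @param subjectMixingSd scale of the per-subject within-hemisphere
#'   channel-mixing perturbation; 0 = identical forward models.
#' @param seed master seed.
#' @return A list of class \code{"GeneratorParams"}.
#' @export
synthParams <- function(channelNames = c("Fp1", "Fp2", "F3", "F4",
                                         "C3", "C4", "P3", "P4",
                                         "O1", "O2", "T7", "T8",
                                         "Cz", "Pz"),
                        fs = 100, durationS = 2.5,
                        nTrialsPerClass = 100L,
                        erdDepth = 0.6,
                        oscillationBand = c(8, 12),
                        backgroundNoiseSd = 1,
                        sourceScale = 2,
                        subjectMixingSd = 0,
                        seed = 1L) {
  if (erdDepth < 0 || erdDepth >= 1)
    stop("erdDepth must lie in [0, 1)")
  if (oscillationBand[2] >= fs / 2)
    stop("oscillation band exceeds the Nyquist frequency")
  nS <- round(fs * durationS)
  if (abs(nS - fs * durationS) > 1e-9)
    stop("fs * durationS must be an integer number of samples")
  structure(list(channelNames = channelNames, fs = fs,
                 durationS = durationS,
                 nTrialsPerClass = as.integer(nTrialsPerClass),
                 erdDepth = erdDepth, oscillationBand = oscillationBand,
                 backgroundNoiseSd = backgroundNoiseSd,
                 sourceScale = sourceScale,
                 subjectMixingSd = subjectMixingSd,
                 seed = as.integer(seed)),
            class = "GeneratorParams")
}

# Fixed source topographies over the default-style montage: loadings on
# the sensorimotor channels of each hemisphere, zero elsewhere (midline
# loading is zero so hemispheric independence holds exactly).
.topographies <- function(channelNames) {
  load1 <- c(C3 = 1, F3 = 0.5, P3 = 0.5, T7 = 0.25)
  load2 <- c(C4 = 1, F4 = 0.5, P4 = 0.5, T8 = 0.25)
  mk <- function(load) {
    t <- stats::setNames(numeric(length(channelNames)), channelNames)
    hit <- intersect(names(load), channelNames)
    if (!length(hit))
      stop("montage has no channels matching the planted topography (",
           paste(names(load), collapse = ", "), ")")
    t[hit] <- load[hit]
    unname(t)
  }
  list(left = mk(load1), right = mk(load2))
}

# Band-limited Gaussian source: white noise band-passed then rescaled to
# unit SD, so trial-to-trial phase and amplitude vary.
.bandSource <- function(nS, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pad <- 2L * round(fs)                  # discard the filter transient
  x <- as.numeric(signal::filter(bf$b, bf$a, stats::rnorm(nS + pad)))
  x <- x[(pad + 1L):(pad + nS)]
  x / stats::sd(x)
}

# Per-subject forward-model perturbation: identity plus Gaussian noise,
# restricted to within-hemisphere blocks so left/right independence of
# the hemispheric signals is preserved.
.mixingMatrix <- function(split, sd, seed) {
  C <- length(split@channelNames)
  M <- diag(C)
  if (sd > 0) {
    withSeed(seed, {
      for (idx in list(split@left, split@right)) {
        n <- length(idx)
        M[idx, idx] <- diag(n) + matrix(stats::rnorm(n * n, sd = sd), n, n)
      }
    })
  }
  M
}

#' Simulate one subject's epoched motor-imagery EEG
#'
#' Draws \code{2 * nTrialsPerClass} labeled trials under the ERD model of
#' \code{\link{synthParams}}. Class 1 trials attenuate the right-hemisphere
#' source (contralateral to imagined left-hand movement), class 2 the left.
#' Identical seeds give bit-identical output.
#'
#' @param params a \code{GeneratorParams} list.
#' @return \code{list(epochs = EpochSet, truth = list)} where \code{truth}
#'   holds the planted topographies, the per-class attenuated channel
#'   index sets, and the subject's mixing matrix.
#' @examples
#' sub <- simulateSubject(synthParams(nTrialsPerClass = 10, seed = 7))
#' sub$epochs
#' @export
simulateSubject <- function(params) {
  stopifnot(inherits(params, "GeneratorParams"))
  ch <- params$channelNames
  C <- length(ch)
  nS <- round(params$fs * params$durationS)
  n <- params$nTrialsPerClass
  topo <- .topographies(ch)
  split <- hemisphereSplit(ch)
  M <- .mixingMatrix(split, params$subjectMixingSd,
                     deriveSeed(params$seed, 90L))
  labels <- rep(1:2, each = n)
  data <- array(0, c(2L * n, C, nS))
  withSeed(deriveSeed(params$seed, 91L), {
    for (i in seq_len(2L * n)) {
      cls <- labels[i]
      ampL <- params$sourceScale *
        (if (cls == 2L) 1 - params$erdDepth else 1)
      ampR <- params$sourceScale *
        (if (cls == 1L) 1 - params$erdDepth else 1)
      sL <- .bandSource(nS, params$fs, params$oscillationBand)
      sR <- .bandSource(nS, params$fs, params$oscillationBand)
      X <- matrix(stats::rnorm(C * nS, sd = params$backgroundNoiseSd),
                  C, nS)
      X <- X + ampL * topo$left %o% sL + ampR * topo$right %o% sR
      data[i, , ] <- M %*% X
    }
  })
  truth <- list(
    topoLeft = topo$left, topoRight = topo$right,
    attenuatedChannels = list(`1` = which(topo$right > 0),
                              `2` = which(topo$left > 0)),
    mixing = M, split = split)
  list(epochs = EpochSet(data, labels, ch, params$fs,
                         classNames = c("left_hand", "right_hand")),
       truth = truth)
}

#' Simulate a cohort of subjects
#'
#' All subjects share the planted source topographies; they differ by
#' their per-subject channel-mixing matrices and by derived seeds. Seeds
#' are derived from the master seed with per-subject counters, so any
#' subject can be regenerated in isolation.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param params a \code{GeneratorParams}; its \code{seed} is the master.
#' @return List of \code{list(epochs, truth)}, one per subject.
#' @export
simulateCohort <- function(nSubjects, params) {
  stopifnot(nSubjects >= 1)
  lapply(seq_len(nSubjects), function(s) {
    p <- params
    p$seed <- deriveSeed(params$seed, 7L, s)
    simulateSubject(p)
  })
}

#' Mean band power per channel
#'
#' Average power of each channel inside a frequency band, estimated from
#' the periodogram and averaged over trials. Used by the generator's own
#' diagnostics and by distribution-matching checks on augmented data.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param band length-2 numeric band in Hz.
#' @param perTrial if TRUE return a trials x channels matrix instead of
#'   the per-channel mean.
#' @return Numeric vector (channels) or matrix (trials x channels).
#' @export
bandPower <- function(epochs, band = c(8, 30), perTrial = FALSE) {
  nS <- nSamples(epochs)
  fs <- samplingRate(epochs)
  freqs <- (seq_len(nS) - 1L) * fs / nS
  sel <- freqs >= band[1] & freqs <= band[2]
  n <- nTrials(epochs); C <- nChannels(epochs)
  out <- matrix(0, n, C)
  for (i in seq_len(n)) {
    X <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = C)
    P <- Mod(t(stats::mvfft(t(X))))^2 / nS
    out[i, ] <- rowMeans(P[, sel, drop = FALSE])
  }
  if (perTrial) out else colMeans(out)
}
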
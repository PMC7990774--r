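# Shared fixtures and independent oracles, built in code at test time.

# Small random EpochSet with balanced two-class labels.
toyEpochs <- function(nPerClass = 5, channels = c("C3", "C4", "P3", "P4"),
                      nSamples = 20, fs = 100, seed = 1) {
  set.seed(seed)
  n <- 2L * nPerClass
  data <- array(rnorm(n * length(channels) * nSamples),
                c(n, length(channels), nSamples))
  EpochSet(data, rep(1:2, each = nPerClass), channels, fs,
           classNames = c("a", "b"))
}

# EpochSet whose channel c is constant at value c (row-selection oracle).
constantEpochs <- function(nTrials = 1, channels = c("A1", "A2", "A3", "A4"),
                           nSamples = 8, fs = 100) {
  C <- length(channels)
  data <- array(0, c(nTrials, C, nSamples))
  for (ch in seq_len(C)) data[, ch, ] <- ch
  EpochSet(data, rep(1L, nTrials), channels, fs, classNames = "a")
}

# Random symmetric positive-definite matrix.
randomSPD <- function(C, seed) {
  set.seed(seed)
  A <- matrix(rnorm(C * C), C)
  crossprod(A) + 0.1 * diag(C)
}

# Two-sample energy-distance permutation test (rows = observations).
# Independent oracle for distribution matching of augmented features.
energyTestP <- function(X, Y, B = 99, seed = 1) {
  Z <- rbind(X, Y)
  n <- nrow(X); m <- nrow(Y)
  D <- as.matrix(dist(Z))
  estat <- function(ix) {
    a <- ix; b <- setdiff(seq_len(n + m), ix)
    2 * mean(D[a, b]) - mean(D[a, a]) - mean(D[b, b])
  }
  obs <- estat(seq_len(n))
  set.seed(seed)
  perm <- replicate(B, estat(sample(n + m, n)))
  (1 + sum(perm >= obs)) / (B + 1)
}

# Brute-force maximization of the Rayleigh quotient w'C1w / w'C2w:
# best of nDirs random unit directions, refined by Nelder-Mead. The
# refinement makes this an optimization oracle independent of any
# eigendecomposition.
rayleighMaxBrute <- function(C1, C2, nDirs = 1e5, seed = 1, refine = TRUE) {
  C <- nrow(C1)
  set.seed(seed)
  W <- matrix(rnorm(C * nDirs), C)
  q <- colSums((C1 %*% W) * W) / colSums((C2 %*% W) * W)
  best <- W[, which.max(q)]
  out <- list(sampled = max(q))
  if (refine) {
    opt <- optim(best, function(w) {
      den <- drop(crossprod(w, C2 %*% w))
      if (den < 1e-12) return(Inf)
      -drop(crossprod(w, C1 %*% w)) / den
    }, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-12))
    out$refined <- -opt$value
  }
  out
}
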
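#' Class covariance matrix of a set of trials
#'
#' Spatial (channels x channels) covariance of one class's trials, either
#' pooled (sum over trials of X X', X the channels x samples trial matrix)
#' or averaged with per-trial trace normalization (mean over trials of
#' X X' / tr(X X')), which is robust to inter-trial amplitude drift. The
#' result is symmetrized as (A + A') / 2.
#'
#' @param epochs an \linkS4class{EpochSet} containing one class's trials
#'   (labels are not consulted; subset first).
#' @param mode "averaged" (trace-normalized, default) or "pooled".
#' @return A list of class \code{"ClassCovariance"}: \code{matrix},
#'   \code{mode}, \code{nTrialsUsed}.
#' @export
classCovariance <- function(epochs, mode = c("averaged", "pooled")) {
  mode <- match.arg(mode)
  n <- nTrials(epochs)
  if (n < 1L) stop("need >= 1 trial to form a covariance")
  C <- nChannels(epochs)
  acc <- matrix(0, C, C)
  for (i in seq_len(n)) {
    X <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = C)
    M <- tcrossprod(X)
    if (mode == "averaged") {
      tr <- sum(diag(M))
      if (tr <= 0) stop(sprintf("trial %d has zero variance", i))
      M <- M / tr
    }
    acc <- acc + M
  }
  if (mode == "averaged") acc <- acc / n
  if (mode == "pooled" && sum(diag(acc)) <= 0)
    stop("degenerate covariance: zero total variance")
  acc <- (acc + t(acc)) / 2
  structure(list(matrix = acc, mode = mode, nTrialsUsed = n),
            class = "ClassCovariance")
}

.covMatrix <- function(x) {
  if (inherits(x, "ClassCovariance")) x$matrix else as.matrix(x)
}

# Generalized eigenproblem C1 w = lambda C2 w via whitening of C2.
# Returns filters (columns, normalized w' C2 w = 1) and eigenvalues,
# descending with a stable tie-break on the original index.
.geig <- function(C1, C2) {
  e2 <- eigen(C2, symmetric = TRUE)
  if (min(e2$values) <= 0)
    stop("denominator covariance not positive definite after ",
         "regularization")
  Wh <- e2$vectors %*% diag(1 / sqrt(e2$values), nrow = length(e2$values))
  S <- t(Wh) %*% C1 %*% Wh
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)  # descending values
  ord <- order(-es$values, seq_along(es$values))
  filters <- Wh %*% es$vectors[, ord, drop = FALSE]
  list(filters = filters, values = es$values[ord])
}

.fixSigns <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Fit common spatial patterns from two class covariances
#'
#' Solves the generalized eigenproblem C1 w = lambda C2 w (C2 ridge-
#' regularized) for the spatial filters extremizing the class variance
#' ratio J(w) = w'C1w / w'C2w. The k filters with the largest eigenvalues
#' form the class-1 block; the class-2 block comes from the swapped problem
#' (C2, C1), equivalently the smallest eigenvalues of the original one.
#' Every filter is normalized so that w' C w = 1 against its own
#' denominator covariance, and signed so its largest-magnitude entry is
#' positive.
#'
#' @param C1,C2 \code{ClassCovariance} objects (or plain matrices) for
#'   classes 1 and 2.
#' @param k filters per class (default 3).
#' @param reg ridge fraction: \code{reg * mean eigenvalue} of the
#'   denominator is added to its diagonal before inversion.
#' @param channelNames optional montage labels stored in the bank.
#' @return A \linkS4class{SpatialFilterBank}.
#' @export
fitCsp <- function(C1, C2, k = 3L, reg = 1e-6, channelNames = character()) {
  M1 <- .covMatrix(C1); M2 <- .covMatrix(C2)
  C <- nrow(M1)
  if (!all(dim(M1) == dim(M2)))
    stop("covariance matrices must have equal dimensions")
  if (2L * k > C)
    stop(sprintf("k = %d too large: need 2k <= %d channels", k, C))
  chk <- function(M, nm) {
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
      stop(nm, " is not symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(abs(M)))
      stop(nm, " is not positive semidefinite")
  }
  chk(M1, "C1"); chk(M2, "C2")
  ridge <- function(M) M + reg * mean(diag(M)) * diag(C)
  g1 <- .geig(M1, ridge(M2))           # maximize class-1/class-2 ratio
  g2 <- .geig(M2, ridge(M1))           # swapped problem for class 2
  filters <- cbind(.fixSigns(g1$filters[, seq_len(k), drop = FALSE]),
                   .fixSigns(g2$filters[, seq_len(k), drop = FALSE]))
  if (length(channelNames)) rownames(filters) <- channelNames
  new("SpatialFilterBank",
      filters = filters,
      eigenvalues = c(g1$values[seq_len(k)], g2$values[seq_len(k)]),
      classOfFilter = rep(1:2, each = as.integer(k)),
      k = as.integer(k),
      channelNames = as.character(channelNames))
}

#' Log normalized-variance CSP features
#'
#' Projects each trial through the 2k spatial filters and returns, per
#' filter f, log(var_f / sum_g var_g) — the log of the normalized variance
#' of the spatially filtered signal. Features are invariant to overall
#' trial amplitude.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param bank a \linkS4class{SpatialFilterBank} over the same montage.
#' @return Numeric matrix, trials x 2k.
#' @export
cspFeatures <- function(epochs, bank) {
  W <- bank@filters
  if (nrow(W) != nChannels(epochs))
    stop(sprintf("filter bank has %d channels but epochs have %d",
                 nrow(W), nChannels(epochs)))
  n <- nTrials(epochs)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    X <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = nChannels(epochs))
    Y <- crossprod(W, X)                 # 2k x T
    v <- apply(Y, 1L, stats::var)
    tot <- sum(v)
    if (tot <= 0) stop(sprintf("trial %d has zero variance after filtering",
                               i))
    out[i, ] <- log(v / tot)
  }
  colnames(out) <- paste0("csp", seq_len(ncol(W)))
  out
}

#' Variance-ratio objective of a spatial filter
#'
#' J(w) = (w' C1 w) / (w' C2 w); scale-invariant in w.
#'
#' @param w numeric filter vector.
#' @param C1,C2 covariance matrices (or \code{ClassCovariance}).
#' @return The Rayleigh quotient value.
#' @export
cspObjective <- function(w, C1, C2) {
  M1 <- .covMatrix(C1); M2 <- .covMatrix(C2)
  drop(crossprod(w, M1 %*% w) / crossprod(w, M2 %*% w))
}
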
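#' Classifier contract
#'
#' Evaluation schemas are classifier-agnostic: any object for which
#' \code{fitClassifier}, \code{predictClassifier} and
#' \code{supportsWarmStart} are defined can be plugged in. \code{state}
#' lets the adaptive schema continue training from a pre-trained state
#' (warm start); classifiers that cannot warm-start must declare it so the
#' adaptive schema can fail with a clear message.
#'
#' @param classifier a classifier description object.
#' @param epochs an \linkS4class{EpochSet} of training or test trials.
#' @param state a fitted state from a previous \code{fitClassifier} call,
#'   or NULL for a cold start.
#' @param seed integer seed for any stochastic element of fitting.
#' @return \code{fitClassifier}: an opaque fitted state.
#'   \code{predictClassifier}: integer predicted labels.
#'   \code{supportsWarmStart}: logical.
#' @name ClassifierContract
NULL

#' @rdname ClassifierContract
#' @export
setGeneric("fitClassifier",
           function(classifier, epochs, state = NULL, seed = 1L)
             standardGeneric("fitClassifier"))
#' @rdname ClassifierContract
#' @export
setGeneric("predictClassifier",
           function(classifier, state, epochs)
             standardGeneric("predictClassifier"))
#' @rdname ClassifierContract
#' @export
setGeneric("supportsWarmStart",
           function(classifier) standardGeneric("supportsWarmStart"))

#' CSP + SVM baseline classifier
#'
#' The traditional motor-imagery decoding pipeline: class covariances,
#' common spatial patterns (k filters per class), log normalized-variance
#' features, and a support-vector machine. The kernel and cost are
#' configuration (the field reports no canonical choice); defaults are an
#' RBF kernel with unit cost. Warm start keeps the pre-trained spatial
#' filter bank fixed and refits only the SVM on the new data's features,
#' which is the natural adaptation step for this pipeline.
#'
#' @slot k CSP filters per class.
#' @slot covMode covariance pooling mode ("averaged" or "pooled").
#' @slot kernel,cost SVM hyperparameters (see \code{\link[e1071]{svm}}).
#' @slot reg CSP ridge fraction.
#' @export
setClass("CspSvmClassifier",
  representation(k = "integer", covMode = "character",
                 kernel = "character", cost = "numeric", reg = "numeric"))

#' @param k CSP filters per class (default 3).
#' @param covMode covariance mode, "averaged" or "pooled".
#' @param kernel,cost SVM kernel and cost.
#' @param reg CSP ridge fraction.
#' @return A \code{CspSvmClassifier} description.
#' @rdname CspSvmClassifier-class
#' @export
cspSvmClassifier <- function(k = 3L, covMode = "averaged",
                             kernel = "radial", cost = 1, reg = 1e-6) {
  new("CspSvmClassifier", k = as.integer(k), covMode = covMode,
      kernel = kernel, cost = cost, reg = reg)
}

.fitCspSvm <- function(classifier, epochs, bank = NULL) {
  labs <- sort(unique(epochs@labels))
  if (length(labs) < 2L)
    stop("training set contains a single class; need two")
  if (is.null(bank)) {
    c1 <- classCovariance(epochs[epochs@labels == labs[1]],
                          mode = classifier@covMode)
    c2 <- classCovariance(epochs[epochs@labels == labs[2]],
                          mode = classifier@covMode)
    bank <- fitCsp(c1, c2, k = classifier@k, reg = classifier@reg,
                   channelNames = epochs@channelNames)
  }
  feat <- cspFeatures(epochs, bank)
  model <- e1071::svm(feat, factor(epochs@labels, levels = labs),
                      kernel = classifier@kernel, cost = classifier@cost,
                      scale = FALSE)
  list(bank = bank, svm = model, levels = labs)
}

#' @rdname ClassifierContract
setMethod("fitClassifier", "CspSvmClassifier",
  function(classifier, epochs, state = NULL, seed = 1L) {
    .fitCspSvm(classifier, epochs,
               bank = if (is.null(state)) NULL else state$bank)
  })

#' @rdname ClassifierContract
setMethod("predictClassifier", "CspSvmClassifier",
  function(classifier, state, epochs) {
    feat <- cspFeatures(epochs, state$bank)
    as.integer(as.character(stats::predict(state$svm, feat)))
  })

#' @rdname ClassifierContract
setMethod("supportsWarmStart", "CspSvmClassifier", function(classifier) TRUE)

#' Majority-vote stub classifier
#'
#' Predicts the most frequent training label for every trial (ties broken
#' toward the smaller label id). A degenerate reference: on a balanced test
#' set its accuracy is exactly the majority class share (0.5 for balanced
#' two-class data). It cannot warm-start.
#'
#' @export
setClass("MajorityClassifier", representation(id = "character"),
         prototype(id = "majority"))

#' @return A \code{MajorityClassifier}.
#' @rdname MajorityClassifier-class
#' @export
majorityClassifier <- function() new("MajorityClassifier")

#' @rdname ClassifierContract
setMethod("fitClassifier", "MajorityClassifier",
  function(classifier, epochs, state = NULL, seed = 1L) {
    tab <- table(epochs@labels)
    list(vote = as.integer(names(tab)[which.max(tab)]))
  })

#' @rdname ClassifierContract
setMethod("predictClassifier", "MajorityClassifier",
  function(classifier, state, epochs) {
    rep(state$vote, nTrials(epochs))
  })

#' @rdname ClassifierContract
setMethod("supportsWarmStart", "MajorityClassifier",
          function(classifier) FALSE)
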
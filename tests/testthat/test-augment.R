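test_that("intra-subject BAR emits the full per-class cartesian product", {
  for (nPer in c(1L, 4L, 10L)) {
    es <- toyEpochs(nPerClass = nPer, seed = nPer)
    sp <- hemisphereSplit(channelNames(es))
    aug <- barIntra(es, sp)
    expect_equal(nTrials(aug), 2L * nPer^2)
    prov <- provenance(aug)
    expect_equal(sum(prov$is_original), 2L * nPer)
    # per-class counts scale as n^2
    expect_equal(as.vector(table(trialLabels(aug))), rep(nPer^2, 2))
    if (nPer == 1L) {
      # only identity pairs exist: augmented set = original set
      expect_equal(sort(epochData(aug)), sort(epochData(es)))
    }
  }
})

test_that("every BAR trial's hemispheric blocks equal their sources exactly", {
  es <- toyEpochs(nPerClass = 6, channels = c("F3", "F4", "C3", "C4",
                                              "Cz", "Pz"), seed = 2)
  sp <- hemisphereSplit(channelNames(es))
  aug <- barIntra(es, sp)
  prov <- provenance(aug)
  for (i in seq_len(nTrials(aug))) {
    expect_identical(epochData(aug)[i, sp@right, ],
                     epochData(es)[prov$right_trial[i], sp@right, ])
    expect_identical(epochData(aug)[i, sp@left, ],
                     epochData(es)[prov$left_trial[i], sp@left, ])
    expect_equal(trialLabels(es)[prov$right_trial[i]], prov$label[i])
    expect_equal(trialLabels(es)[prov$left_trial[i]], prov$label[i])
  }
})

test_that("BAR output order is deterministic by (class, right, left)", {
  es <- toyEpochs(nPerClass = 3, seed = 7)
  sp <- hemisphereSplit(channelNames(es))
  p <- provenance(barIntra(es, sp))
  expect_false(is.unsorted(p$label))
  for (cl in 1:2) {
    pc <- p[p$label == cl, ]
    expect_false(is.unsorted(pc$right_trial))
  }
  expect_identical(provenance(barIntra(es, sp)), p)
})

test_that("the per-class cap subsamples reproducibly, keeping identity pairs", {
  es <- toyEpochs(nPerClass = 8, seed = 3)
  sp <- hemisphereSplit(channelNames(es))
  aug <- barIntra(es, sp, maxPairsPerClass = 20L, seed = 5)
  expect_equal(nTrials(aug), 40L)
  expect_equal(sum(provenance(aug)$is_original), 16L)
  aug2 <- barIntra(es, sp, maxPairsPerClass = 20L, seed = 5)
  expect_identical(epochData(aug), epochData(aug2))
  aug3 <- barIntra(es, sp, maxPairsPerClass = 20L, seed = 6)
  expect_false(identical(provenance(aug), provenance(aug3)))
  expect_error(barIntra(es, sp, maxPairsPerClass = 5L), "identity")
})

test_that("BAR errors on an absent class and mismatched split", {
  es <- toyEpochs(nPerClass = 3)
  onlyClass1 <- es[trialLabels(es) == 1L]
  sp <- hemisphereSplit(channelNames(es))
  expect_error(barIntra(onlyClass1, sp), "no trials")
  expect_error(barIntra(es, hemisphereSplit(c("C3", "C4"))),
               "montage|channels")
})

test_that("right-half marginal is conserved: each source appears n_c times", {
  es <- toyEpochs(nPerClass = 5, seed = 11)
  sp <- hemisphereSplit(channelNames(es))
  aug <- barIntra(es, sp)
  hashRow <- function(arr, i, idx)
    paste(signif(arr[i, idx, ], 12), collapse = ",")
  for (cl in 1:2) {
    gen <- which(trialLabels(aug) == cl)
    counts <- table(vapply(gen, function(i)
      hashRow(epochData(aug), i, sp@right), ""))
    expect_true(all(counts == 5L))
    src <- which(trialLabels(es) == cl)
    srcHashes <- vapply(src, function(i)
      hashRow(epochData(es), i, sp@right), "")
    expect_setequal(names(counts), srcHashes)
  }
})

test_that("multi-subject BAR unions all ordered source pairs, never the target", {
  sets <- lapply(1:4, function(s) toyEpochs(nPerClass = 10, seed = 100 + s))
  sp <- hemisphereSplit(channelNames(sets[[1]]))
  aug <- barMulti(sets, excludedSubject = 2L, split = sp)
  expect_equal(nTrials(aug), 2L * (3L * 10L)^2)
  prov <- provenance(aug)
  expect_false(any(prov$right_subject == 2L | prov$left_subject == 2L))
  # duplicate-free as (right_source, left_source, class) triples
  key <- with(prov, paste(right_subject, right_trial, left_subject,
                          left_trial, label))
  expect_false(any(duplicated(key)))
})

test_that("two-subject multi BAR degenerates to the source's intra BAR", {
  sets <- lapply(1:2, function(s) toyEpochs(nPerClass = 4, seed = 200 + s))
  sp <- hemisphereSplit(channelNames(sets[[1]]))
  multi <- barMulti(sets, excludedSubject = 1L, split = sp)
  intra <- barIntra(sets[[2]], sp, subject = 2L)
  expect_identical(epochData(multi), epochData(intra))
  expect_identical(provenance(multi)[, -1], provenance(intra)[, -1])
})

test_that("disallowing same-source pairs drops within-subject products", {
  sets <- lapply(1:3, function(s) toyEpochs(nPerClass = 3, seed = 300 + s))
  sp <- hemisphereSplit(channelNames(sets[[1]]))
  aug <- barMulti(sets, excludedSubject = 3L, split = sp,
                  allowSameSource = FALSE)
  prov <- provenance(aug)
  expect_false(any(prov$right_subject == prov$left_subject))
  # 2 sources, ordered i != j pairs: 2 * n^2 per class per direction
  expect_equal(nTrials(aug), 2L * 2L * 3L^2)
  expect_error(barMulti(sets[1], 1L, sp), ">= 2 subjects")
})

test_that("time flipping doubles the set and reverses samples", {
  es <- toyEpochs(nPerClass = 4, seed = 13)
  aug <- flipTime(es)
  n <- nTrials(es); S <- nSamples(es)
  expect_equal(nTrials(aug), 2L * n)
  expect_equal(trialLabels(aug), rep(trialLabels(es), 2))
  expect_identical(epochData(aug)[n + 1, 1, ], rev(epochData(es)[1, 1, ]))
  # involution: flipping the generated block recovers the originals
  gen <- aug[(n + 1):(2 * n)]
  back <- flipTime(gen)
  expect_identical(epochData(back)[(n + 1):(2 * n), , ], epochData(es))
})

test_that("flipping preserves every trial's FFT magnitude spectrum", {
  es <- toyEpochs(nPerClass = 3, seed = 17)
  n <- nTrials(es)
  aug <- flipTime(es)
  for (i in seq_len(n)) for (ch in seq_len(nChannels(es))) {
    mOrig <- Mod(fft(epochData(es)[i, ch, ]))
    mFlip <- Mod(fft(epochData(aug)[n + i, ch, ]))
    expect_equal(mFlip, mOrig, tolerance = 1e-9)
  }
})

test_that("noise augmentation enforces the linear SNR per trial", {
  es <- toyEpochs(nPerClass = 10, seed = 19)
  n <- nTrials(es)
  aug <- addNoise(es, snr = 5, mode = "v1", seed = 4)
  expect_equal(nTrials(aug), 2L * n)
  for (i in seq_len(n)) {
    x <- epochData(es)[i, , ]
    noise <- epochData(aug)[n + i, , ] - x
    expect_equal(var(as.vector(x)) / var(as.vector(noise)), 5,
                 tolerance = 1e-6)
  }
  # dB interpretation: 7 dB ~ 10^0.7 linear
  augDb <- addNoise(es, snr = 7, mode = "v1", seed = 4, snrInDb = TRUE)
  x <- epochData(es)[1, , ]
  noise <- epochData(augDb)[n + 1, , ] - x
  expect_equal(var(as.vector(x)) / var(as.vector(noise)), 10^0.7,
               tolerance = 1e-6)
})

test_that("noise v2 matches the BAR expansion and validates its target", {
  es <- toyEpochs(nPerClass = 6, seed = 23)
  target <- 2L * 6L^2
  aug <- addNoise(es, snr = 5, mode = "v2", targetSize = target, seed = 9)
  expect_equal(nTrials(aug), target)
  prov <- provenance(aug)
  expect_equal(sum(prov$is_original), nTrials(es))
  # resampled sources carry their source's label
  gen <- which(!prov$is_original)
  expect_equal(trialLabels(aug)[gen], trialLabels(es)[prov$right_trial[gen]])
  expect_error(addNoise(es, mode = "v2", targetSize = 5L), "targetSize")
  expect_error(addNoise(es, mode = "v2"), "targetSize")
  expect_error(addNoise(es, snr = -1), "positive")
})

test_that("noise augmentation is seeded and reproducible", {
  es <- toyEpochs(nPerClass = 5, seed = 29)
  a <- addNoise(es, seed = 7)
  b <- addNoise(es, seed = 7)
  c <- addNoise(es, seed = 8)
  expect_identical(epochData(a), epochData(b))
  expect_false(identical(epochData(a), epochData(c)))
})

test_that("BAR trials match the originals' per-class band-power profile", {
  # on generator data hemispheres are class-conditionally independent, so
  # recombination leaves per-channel mean band power unchanged up to
  # Monte-Carlo error
  sub <- simulateSubject(synthParams(nTrialsPerClass = 40, seed = 31))
  es <- sub$epochs
  sp <- hemisphereSplit(channelNames(es))
  aug <- barIntra(es, sp)
  for (cl in 1:2) {
    orig <- bandPower(es[trialLabels(es) == cl], c(8, 30), perTrial = TRUE)
    gen <- bandPower(aug[trialLabels(aug) == cl], c(8, 30),
                     perTrial = TRUE)
    se <- apply(orig, 2, sd) / sqrt(nrow(orig))
    expect_true(all(abs(colMeans(gen) - colMeans(orig)) <= 3 * se))
  }
})
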
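test_that("generators are bit-deterministic per seed and vary across
           seeds", {
  a <- genLoopCurve(24, seed = 3, noiseSd = 0.1)
  b <- genLoopCurve(24, seed = 3, noiseSd = 0.1)
  c <- genLoopCurve(24, seed = 4, noiseSd = 0.1)
  expect_identical(caCoords(a$structure), caCoords(b$structure))
  expect_false(identical(caCoords(a$structure), caCoords(c$structure)))
  p1 <- genPeptideTable(nProteins = 50, seed = 2)
  p2 <- genPeptideTable(nProteins = 50, seed = 2)
  expect_identical(p1$peptides, p2$peptides)
  q1 <- genQgSeries(list(c(0.9, 0.1)), 1, nFrames = 100, seed = 5)
  q2 <- genQgSeries(list(c(0.9, 0.1)), 1, nFrames = 100, seed = 5)
  expect_identical(q1$qg, q2$qg)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(genPeptideTable(nProteins = 20, seed = 9))
  expect_identical(runif(1), before)
})

test_that("both mini-protein motifs build valid Go models", {
  for (m in c("helix_hairpin", "entangled_hairpin")) {
    s <- genMiniProtein(m, seed = 1)$structure
    gm <- buildGoModel(s, heavyAtomContacts(s, cutoff = 8))
    expect_equal(gm@n, nResidues(s))
    expect_true(is.finite(goEnergy(gm)$energy))
  }
})

test_that("peptide-table generator plants the requested protein-level OR", {
  fx <- genPeptideTable(nProteins = 5000, prevalenceExposed = 0.3,
                        prevalenceUnexposed = 0.176, seed = 31)
  expect_equal(fx$truth$proteinOR, 2.0, tolerance = 0.01)
  # the peptide pathway reproduces the planted protein labels exactly
  calls <- classifyProteinChange(fx$peptides)[fx$proteins$protein]
  expect_equal(unname(calls), fx$proteins$changed)
  # Woolf CI covers the planted OR at ~95%: require >= 21 of 25 seeds
  hits <- sum(vapply(1:25, function(s) {
    g <- genPeptideTable(nProteins = 5000, prevalenceExposed = 0.3,
                         prevalenceUnexposed = 0.176, emitPeptides = FALSE,
                         seed = 300 + s)
    r <- contingency(g$proteins$entangled, g$proteins$changed)
    r@ciLow <= 2 && 2 <= r@ciHigh
  }, logical(1)))
  expect_gte(hits, 21)
  # equal prevalences: OR CIs cover 1 at the same rate
  hits0 <- sum(vapply(1:25, function(s) {
    g <- genPeptideTable(nProteins = 5000, prevalenceExposed = 0.2,
                         prevalenceUnexposed = 0.2, emitPeptides = FALSE,
                         seed = 600 + s)
    r <- contingency(g$proteins$entangled, g$proteins$changed)
    r@ciLow <= 1 && 1 <= r@ciHigh
  }, logical(1)))
  expect_gte(hits0, 21)
})

test_that("confounded mode biases the crude OR but not the adjusted one", {
  beta <- c(-2, log(2), 0.8)
  fx <- genPeptideTable(nProteins = 20000, beta = beta, confounded = TRUE,
                        seed = 33)
  crude <- oddsRatio(contingency(fx$proteins$entangled,
                                 fx$proteins$changed))
  adj <- adjustedOR(fx$proteins$changed, fx$proteins$entangled,
                    fx$proteins$length)
  expect_gt(crude, exp(beta[2]) * 1.15)        # visibly biased upward
  expect_true(adj@ciLow <= exp(beta[2]) && exp(beta[2]) <= adj@ciHigh)
})

test_that("Q/G series recovers planted populations and is label-order
           invariant", {
  fx <- genQgSeries(list(c(0.95, 0.02), c(0.9, 0.3)), c(0.7, 0.3),
                    nFrames = 6000, seed = 12)
  pops <- as.numeric(table(fx$labels) / length(fx$labels))
  expect_lt(max(abs(pops - c(0.7, 0.3))), 0.05)
  fxSwap <- genQgSeries(list(c(0.9, 0.3), c(0.95, 0.02)), c(0.3, 0.7),
                        nFrames = 6000, seed = 12)
  popsSwap <- as.numeric(table(fxSwap$labels) / length(fxSwap$labels))
  expect_lt(max(abs(sort(pops) - sort(popsSwap))), 0.05)
  expect_warning(genQgSeries(list(c(0.9, 0.1), c(0.905, 0.1)), c(0.5, 0.5),
                             nFrames = 50, noiseSd = 0.05, seed = 1),
                 "overlap")
})

test_that("SASA ensemble generator shifts only the requested site windows", {
  fx <- genSasaEnsembles(nNative = 200, nMis = 200, nSites = 3,
                         shiftSites = 3, shiftMagnitude = 1.5, seed = 13)
  shifted <- sasaWindow(fx$mis, fx$sites[3])
  unshifted <- sasaWindow(fx$mis, fx$sites[1])
  refShift <- sasaWindow(fx$native, fx$sites[3])
  expect_gt(mean(shifted) - mean(refShift), 8)
  expect_lt(abs(mean(unshifted) - mean(sasaWindow(fx$native,
                                                  fx$sites[1]))), 3)
})

test_that("ground truth serializes to sidecar JSON", {
  fx <- genPeptideTable(nProteins = 20, seed = 1)
  f <- tempfile(fileext = ".json")
  writeTruthJson(fx$truth, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$proteinOR, fx$truth$proteinOR, tolerance = 1e-12)
})
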
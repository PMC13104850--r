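test_that("Q is 1 at the native frame, 0 when expanded, and counts the
           boundary as formed", {
  fx <- goFixture()
  np <- fx$model@pairs
  ca <- caCoords(fx$structure)
  expect_equal(computeQ(ca, np), 1)
  expect_equal(computeQ(ca * 3, np), 0)
  # hand-built contact list: half the pairs exactly at 1.2 r0, half at 2 r0
  frame <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 50, 0), c(20, 50, 0))
  pairs <- rbind(c(1, 2, 10), c(3, 4, 10))
  expect_equal(computeQ(frame, pairs), 0.5)
  expect_error(computeQ(frame, pairs[0, , drop = FALSE]), "empty")
})

test_that("Q is rigid-motion invariant and non-increasing under expansion", {
  fx <- goFixture()
  np <- fx$model@pairs
  ca <- caCoords(fx$structure)
  ca2 <- sweep(ca %*% randomRotation(3), 2, c(1, 2, 3), "+")
  expect_equal(computeQ(ca2, np), 1)
  qs <- vapply(c(1, 1.1, 1.25, 1.5, 2), function(s) computeQ(ca * s, np),
               numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("G is 0 at the native frame and flags chirality flips and lost
           threads", {
  mp <- genMiniProtein("entangled_hairpin", seed = 1)
  cm <- heavyAtomContacts(mp$structure)
  np <- nativePairsFromMap(mp$structure, cm)
  ca <- caCoords(mp$structure)
  ref <- referenceLinking(ca, np)
  expect_equal(computeG(ca, ref), 0)
  # mirrored frame: every chirally-linked contact flips its rounded g
  cam <- ca; cam[, 3] <- -cam[, 3]
  nLinked <- sum(round(ref$gN) != 0 | round(ref$gC) != 0)
  expect_equal(computeG(cam, ref), nLinked / nrow(np))
  # pull the thread out of the loop: the linked contacts lose entanglement
  tailIdx <- (mp$truth$loop[2] + 1):nrow(ca)
  caOut <- ca
  caOut[tailIdx, ] <- cbind(seq_along(tailIdx) * 3.8 + 40, 0, 6)
  gOut <- computeG(caOut, ref)
  expect_equal(gOut, nLinked / nrow(np))
  expect_error(computeG(ca[-1, ], ref), "length")
})

test_that("microstate/macrostate clustering recovers planted two-state
           structure", {
  fx <- genQgSeries(list(c(0.95, 0.02), c(0.5, 0.45)),
                    populations = c(0.7, 0.3), nFrames = 4000, seed = 3)
  a <- clusterStates(fx$qg, kMicro = 50, nMacro = 2, seed = 1)
  # map planted labels to macrostates by majority and check accuracy
  tab <- table(fx$labels, a@macro)
  acc <- sum(apply(tab, 1, max)) / length(fx$labels)
  expect_gte(acc, 0.99)
  # native macrostate is the high-Q low-G one
  expect_equal(a@nativeMacro,
               unname(a@macro[which.max(fx$qg[, 1] - fx$qg[, 2])]))
})

test_that("single-cluster data yields one macrostate under auto selection", {
  fx <- genQgSeries(list(c(0.9, 0.05)), populations = 1, nFrames = 1500,
                    seed = 4)
  expect_warning(a <- clusterStates(fx$qg, kMicro = 40, nMacro = "auto",
                                    seed = 1), NA)
  expect_equal(length(unique(a@macro)), 1)
})

test_that("clustering is deterministic per seed and warns when frames are
           scarce", {
  fx <- genQgSeries(list(c(0.9, 0.05), c(0.5, 0.4)), c(0.5, 0.5),
                    nFrames = 300, seed = 5)
  a1 <- clusterStates(fx$qg, kMicro = 30, nMacro = 2, seed = 7)
  a2 <- clusterStates(fx$qg, kMicro = 30, nMacro = 2, seed = 7)
  expect_identical(a1@centers, a2@centers)
  expect_identical(a1@macro, a2@macro)
  expect_warning(clusterStates(fx$qg[1:50, ], kMicro = 100, nMacro = 2,
                               seed = 1), "fewer frames")
})

test_that("misfolding probability implements the counting identity", {
  fx <- genQgSeries(list(c(0.95, 0.02), c(0.9, 0.35)),
                    populations = c(0.7, 0.3), nFrames = 20000, dwell = 8,
                    seed = 6)
  a <- clusterStates(fx$qg, kMicro = 50, nMacro = 2, seed = 1)
  m <- misfoldingProbability(a, qFloor = 0.6)
  expect_equal(m@pMis, 100 * m@nMis / (m@nMis + m@nNative))
  expect_lt(abs(m@pMis - 30), 2)
  # all-native window
  win <- which(a@macro == a@nativeMacro)
  expect_equal(misfoldingProbability(a, window = win)@pMis, 0)
  # pooled P_mis equals the frame-weighted mean over two disjoint windows
  w1 <- 1:10000; w2 <- 10001:20000
  m1 <- misfoldingProbability(a, w1); m2 <- misfoldingProbability(a, w2)
  tot1 <- m1@nMis + m1@nNative; tot2 <- m2@nMis + m2@nNative
  pooled <- misfoldingProbability(a)
  expect_equal(pooled@pMis,
               (m1@pMis * tot1 + m2@pMis * tot2) / (tot1 + tot2))
})
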
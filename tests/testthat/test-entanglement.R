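test_that("linking number of a threaded circle matches the dense oracle", {
  fx <- genLoopCurve(24, threaded = TRUE, seed = 1)
  ca <- caCoords(fx$structure)
  g <- gaussLinking(ca, fx$loop)
  # oracle: dense numerical Gauss double integral over the same two curves
  loopPts <- ca[fx$loop[1]:fx$loop[2], ]
  tailPts <- ca[(fx$loop[2] + 1):nrow(ca), ]
  oracle <- denseLinkingOracle(loopPts, tailPts)
  expect_equal(abs(g$gC), 1, tolerance = 0.05)
  expect_equal(g$gC, oracle, tolerance = 0.06)
  expect_equal(g$gN, 0)  # empty N-tail window gives exactly zero
})

test_that("a coplanar outside tail is unlinked", {
  fx <- genLoopCurve(24, threaded = FALSE, seed = 1)
  g <- gaussLinking(caCoords(fx$structure), fx$loop)
  expect_lt(abs(g$gC), 0.1)
})

test_that("mirroring flips the sign of g exactly", {
  for (s in 1:3) {
    fx <- genLoopCurve(24, threaded = TRUE, seed = s, noiseSd = 0.1)
    ca <- caCoords(fx$structure)
    g <- gaussLinking(ca, fx$loop)
    cam <- ca; cam[, 3] <- -cam[, 3]
    gm <- gaussLinking(cam, fx$loop)
    expect_identical(gm$gC, -g$gC)
    expect_identical(gm$gN, -g$gN)
  }
})

test_that("linking is invariant under rigid motion", {
  fx <- genLoopCurve(24, threaded = TRUE, seed = 2, noiseSd = 0.05)
  ca <- caCoords(fx$structure)
  g1 <- gaussLinking(ca, fx$loop)$gC
  ca2 <- sweep(ca %*% randomRotation(11), 2, c(5, 6, -7), "+")
  expect_equal(gaussLinking(ca2, fx$loop)$gC, g1, tolerance = 1e-10)
})

test_that("planted linking numbers are recovered under rotation and jitter", {
  cases <- list(c(0, 1), c(1, 1), c(1, -1), c(2, 1), c(2, -1))
  ok <- 0; tot <- 0
  for (L in cases) for (s in 1:40) {
    fx <- genLoopCurve(24, threaded = L[1] > 0, turns = max(1, L[1]),
                       chirality = L[2], noiseSd = 0.1, seed = s)
    ca <- caCoords(fx$structure) %*% randomRotation(1000 + s)
    g <- gaussLinking(ca, fx$loop)
    tot <- tot + 1
    if (round(g$gC) == fx$truth$linking) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.99)
})

test_that("partial profile accumulates to the full linking value", {
  fx <- genLoopCurve(24, threaded = TRUE, seed = 1)
  ca <- caCoords(fx$structure)
  prof <- partialLinkingProfile(ca, fx$loop, "C")
  g <- gaussLinking(ca, fx$loop)
  expect_equal(unname(prof[length(prof)]), g$gC, tolerance = 1e-12)
  # rises from ~0 through 0.5 exactly once
  crossings <- sum(diff(c(0, prof) > 0.5) == 1)
  expect_equal(crossings, 1)
  # unthreaded profile never exceeds 0.5
  fx0 <- genLoopCurve(24, threaded = FALSE, seed = 1)
  prof0 <- partialLinkingProfile(caCoords(fx0$structure), fx0$loop, "C")
  expect_lt(max(abs(prof0)), 0.5)
})

test_that("crossing detection localizes the piercing with its sign", {
  fx <- genLoopCurve(24, threaded = TRUE, seed = 1)
  prof <- partialLinkingProfile(caCoords(fx$structure), fx$loop, "C")
  cr <- findCrossings(prof)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$sign, 1)
  fx0 <- genLoopCurve(24, threaded = FALSE, seed = 1)
  prof0 <- partialLinkingProfile(caCoords(fx0$structure), fx0$loop, "C")
  expect_equal(nrow(findCrossings(prof0)), 0)
  fx2 <- genLoopCurve(24, threaded = TRUE, turns = 2, seed = 1)
  cr2 <- findCrossings(
    partialLinkingProfile(caCoords(fx2$structure), fx2$loop, "C"))
  expect_equal(nrow(cr2), 2)
  expect_equal(unique(cr2$sign), 1)
})

test_that("slipknots are cancelling crossings, multi-threading is not", {
  expect_true(isSlipknot(data.frame(residue = c(40, 50),
                                    sign = c(1, -1)), g = 0.3))
  expect_false(isSlipknot(data.frame(residue = 40, sign = 1), g = 0.9))
  expect_false(isSlipknot(data.frame(residue = c(40, 50),
                                     sign = c(1, 1)), g = 1.9))
})

test_that("NCLE detection finds exactly the planted entanglement", {
  mh <- genMiniProtein("helix_hairpin", seed = 1)$structure
  expect_length(detectNcles(mh, heavyAtomContacts(mh)), 0)

  mp <- genMiniProtein("entangled_hairpin", seed = 1)
  cm <- heavyAtomContacts(mp$structure)
  nc <- detectNcles(mp$structure, cm)
  expect_gte(length(nc), 1)
  nc <- clusterNcles(nc)
  reps <- Filter(function(x) x@representative, nc)
  expect_length(reps, 1)
  expect_equal(unname(reps[[1]]@loop), mp$truth$loop)
  expect_equal(reps[[1]]@crossings$residue, mp$truth$crossing,
               tolerance = 2)
  # threshold above the planted |g| finds nothing; monotone in threshold
  expect_length(detectNcles(mp$structure, cm, threshold = 1.1), 0)
  expect_lte(length(detectNcles(mp$structure, cm, threshold = 0.8)),
             length(nc))
})

test_that("degenerate NCLEs cluster and the shortest loop represents", {
  mk <- function(i, j, cross) new("NCLE", loop = c(i, j), gN = 0, gC = 0.9,
    crossings = data.frame(residue = cross, sign = 1L, terminus = "C"),
    representative = FALSE, clusterId = NA_integer_)
  out <- clusterNcles(list(mk(10L, 50L, 60L), mk(12L, 48L, 60L)))
  expect_equal(out[[1]]@clusterId, out[[2]]@clusterId)
  expect_false(out[[1]]@representative)
  expect_true(out[[2]]@representative)  # shorter loop (12, 48) wins
  out2 <- clusterNcles(list(mk(10L, 50L, 60L), mk(12L, 48L, 80L)))
  expect_equal(length(unique(vapply(out2, function(x) x@clusterId,
                                    integer(1)))), 2)
})

test_that("entangled-region mask is the buffered union plus spatial shell", {
  # straight chain: spatial neighbours of key residues are already inside
  # the +/-3 sequence buffer, so the mask is the pure buffer union
  ca <- cbind(seq_len(40) * 3.8, 0, 0)
  s <- structureFromCa(ca)
  nc <- new("NCLE", loop = c(10L, 20L), gN = 0, gC = 1,
            crossings = data.frame(residue = 30L, sign = 1L,
                                   terminus = "C"),
            representative = TRUE, clusterId = 1L)
  m <- entangledRegionMask(s, list(nc))
  expect_equal(which(m@mask), c(7:13, 17:23, 27:33))
  # crossing near the terminus: neighbourhood clipped, no error
  nc2 <- new("NCLE", loop = c(10L, 20L), gN = 0, gC = 1,
             crossings = data.frame(residue = 2L, sign = 1L,
                                    terminus = "N"),
             representative = TRUE, clusterId = 1L)
  m2 <- entangledRegionMask(s, list(nc2))
  expect_true(all(m2@mask[1:5]))
  # brute-force oracle on a folded fixture with real spatial contacts
  mp <- genMiniProtein("entangled_hairpin", seed = 1)
  cm <- heavyAtomContacts(mp$structure)
  nc3 <- clusterNcles(detectNcles(mp$structure, cm))
  m3 <- entangledRegionMask(mp$structure, nc3)
  rep3 <- Filter(function(x) x@representative, nc3)[[1]]
  key <- sort(unique(c(rep3@loop, rep3@crossings$residue)))
  caP <- caCoords(mp$structure)
  expected <- rep(FALSE, nrow(caP))
  for (r in key)
    expected[max(1, r - 3):min(nrow(caP), r + 3)] <- TRUE
  for (r in seq_len(nrow(caP)))
    if (min(sqrt(colSums((t(caP[key, , drop = FALSE]) - caP[r, ])^2))) <= 4.5)
      expected[r] <- TRUE
  expect_equal(m3@mask, expected)
})
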
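test_that("nodeVolume is the weighted degree", {
  w <- matrix(0, 4, 4, dimnames = rep(list(c("c", "x", "y", "z")), 2))
  w["c", c("x", "y", "z")] <- 1
  w[c("x", "y", "z"), "c"] <- 1
  g <- Connectome(w)
  expect_equal(unname(nodeVolume(g, "c")), 3)
  expect_equal(unname(nodeVolume(g, "x")), 1)
  expect_error(nodeVolume(g, "q"), "unknown")

  iso <- Connectome(matrix(0, 2, 2))
  expect_equal(unname(nodeVolume(iso, "n1")), 0)

  # handshake identity: volumes sum to twice the unique-edge weight
  g2 <- randomConnectome(9, density = 0.5, seed = 6)
  expect_equal(sum(nodeVolume(g2)),
               2 * sum(adjacency(g2)[upper.tri(diag(9))]))
})

test_that("pathContribution follows the damped-volume recursion", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("u", "v", "w")), 2))
  w["u", "v"] <- w["v", "u"] <- 2
  w["v", "w"] <- w["w", "v"] <- 3
  g <- Connectome(w)
  expect_equal(pathContribution(g, "u"), 2)              # vol(u)
  expect_equal(pathContribution(g, c("u", "w")), 0)      # non-edge
  expect_equal(pathContribution(g, c("u", "v", "w")), (2 / 2) * (3 / 5) * 3)
  expect_error(pathContribution(g, c("u", "q")), "unknown")

  # agrees with the independent recursion on random graphs
  set.seed(17)
  g2 <- randomConnectome(8, density = 0.7, seed = 17)
  w2 <- adjacency(g2)
  for (i in 1:20) {
    pth <- sample(nodeLabels(g2), sample(1:4, 1))
    expect_equal(pathContribution(g2, pth),
                 oracleF(w2, match(pth, nodeLabels(g2))))
  }
})

test_that("wlSignature matches the exhaustive path-enumeration oracle", {
  # closed-form check on the two-level star example (strict rankings)
  g <- signatureExampleGraph()
  H <- wlSignature(g, "u", wlParams(8, width = 2, depth = 2))
  expect_length(H, 7)
  expect_equal(H[1], unname(nodeVolume(g, "u")))
  volU <- 5; volV1 <- 6.7; volV2 <- 6.5
  expect_equal(H, c(
    volU,
    volV1 * 4 / volU,                 # hop to v1
    volV2 * 1 / volU,                 # hop to v2
    volU * (4 / volV1) * (4 / volU),  # v1 back to u
    1.0 * (1.0 / volV1) * (4 / volU), # v1 -> w1
    3 * (3 / volV2) * (1 / volU),     # v2 -> w4
    2.5 * (2.5 / volV2) * (1 / volU)  # v2 -> w5
  ))
  expect_equal(H, oracleSignature(adjacency(g), 1L, 2L, 2L))

  # random continuous-weight graphs, several (width, depth) settings
  for (s in 1:3) {
    g2 <- randomConnectome(9, density = 0.8, seed = 70 + s)
    A <- adjacency(g2)
    for (k in c(1L, 2L, 3L)) {
      for (ell in c(0L, 1L, 2L)) {
        prm <- wlParams(9, width = k, depth = ell)
        for (u in c(1L, 5L)) {
          expect_equal(wlSignature(g2, nodeLabels(g2)[u], prm),
                       oracleSignature(A, u, k, ell))
        }
      }
    }
  }
})

test_that("signature length is sum of width powers for any parameters", {
  g <- randomConnectome(12, density = 0.6, seed = 8)
  for (k in c(1, 2, 4)) {
    for (ell in c(0, 1, 3)) {
      S <- signatureTable(g, wlParams(12, width = k, depth = ell))
      expect_equal(dim(S), c(12L, sum(k^(0:ell))))
      expect_equal(unname(S[, 1]), unname(nodeVolume(g)))
    }
  }
  # width exceeding n - 1: padded with zero-contribution entries
  S <- signatureTable(randomConnectome(4, density = 1, seed = 1),
                      wlParams(4, width = 6, depth = 1))
  expect_equal(ncol(S), 7L)
})

test_that("signatureTable is deterministic and consistent with wlSignature", {
  g <- randomConnectome(10, density = 0.5, seed = 14)
  prm <- wlParams(10, seed = 99)
  S1 <- signatureTable(g, prm)
  S2 <- signatureTable(g, prm)
  expect_identical(S1, S2)
  for (u in nodeLabels(g)[c(1, 4, 10)]) {
    expect_identical(wlSignature(g, u, prm), unname(S1[u, ]))
  }
})

test_that("automorphic nodes share a signature", {
  # two leaves attached to the same hub with equal weights
  w <- matrix(0, 4, 4, dimnames = rep(list(c("h", "l1", "l2", "x")), 2))
  w["h", "l1"] <- w["l1", "h"] <- 2
  w["h", "l2"] <- w["l2", "h"] <- 2
  w["h", "x"] <- w["x", "h"] <- 5
  g <- Connectome(w)
  S <- signatureTable(g, wlParams(4, width = 2, depth = 2))
  expect_equal(S["l1", ], S["l2", ])
})

test_that("signatures are permutation-equivariant under strict rankings", {
  for (s in 1:5) {
    g <- randomConnectome(10, density = 0.7, seed = 120 + s)
    p <- permuteConnectome(g, seed = 140 + s)
    prm <- wlParams(10)
    S <- signatureTable(g, prm)
    Sp <- signatureTable(p$connectome, prm)
    m <- alignmentMap(p$truth)
    for (u in nodeLabels(g)) {
      expect_equal(unname(S[u, ]), unname(Sp[m[u], ]))
    }
  }
})

test_that("bipartiteCost is the Euclidean distance between signatures", {
  s1 <- rbind(a = c(1, 0), b = c(0, 1))
  s2 <- rbind(x = c(1, 0), y = c(0, 1))
  d <- bipartiteCost(s1, s2)
  expect_equal(unname(d), matrix(c(0, sqrt(2), sqrt(2), 0), 2, 2))
  expect_true(all(d >= 0))
  expect_error(bipartiteCost(s1, cbind(s2, 0)), "length")

  g <- randomConnectome(7, density = 0.8, seed = 5)
  S <- signatureTable(g, wlParams(7))
  d2 <- bipartiteCost(S, S)
  expect_equal(unname(diag(d2)), rep(0, 7))
  expect_equal(d2["n001", "n004"], sqrt(sum((S[1, ] - S[4, ])^2)))
})

test_that("solveAssignment reaches the exhaustive optimum", {
  cost <- matrix(5, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  diag(cost) <- 0
  a <- solveAssignment(cost)
  expect_equal(alignmentMap(a), c(a = "A", b = "B", c = "C"))
  expect_equal(attr(a, "totalCost"), 0)

  set.seed(44)
  for (i in 1:30) {
    n <- sample(2:7, 1)
    cost <- matrix(runif(n * n), n, n,
                   dimnames = list(paste0("s", 1:n), paste0("t", 1:n)))
    got <- attr(solveAssignment(cost), "totalCost")
    expect_equal(got, oracleAssignmentCost(cost), tolerance = 1e-10)
  }

  # permuting the rows permutes the alignment identically
  cost <- matrix(runif(16), 4, 4,
                 dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  base <- alignmentMap(solveAssignment(cost))
  perm <- c(3, 1, 4, 2)
  shuffled <- alignmentMap(solveAssignment(cost[perm, ]))
  expect_equal(shuffled[names(base)], base)

  expect_error(solveAssignment(matrix(numeric(0), 0, 0)), "empty")
  expect_error(solveAssignment(matrix(1, 3, 2)), "nrow")
})

test_that("rectangular assignment injects rows into columns optimally", {
  cost <- matrix(c(1, 9, 9, 9, 9, 1, 5, 5, 5), 3, 3)[1:2, ]
  dimnames(cost) <- list(c("a", "b"), c("X", "Y", "Z"))
  a <- solveAssignment(cost)
  expect_length(alignmentMap(a), 2)
  expect_equal(attr(a, "totalCost"), oracleAssignmentCost(cost))
})

test_that("wlAlign recovers identity and random permutations exactly", {
  g <- randomConnectome(20, density = 0.5, seed = 31)
  self <- wlAlign(g, g)
  expect_equal(alignmentMap(self),
               stats::setNames(nodeLabels(g), nodeLabels(g)))

  for (s in 1:5) {
    g <- normalizeWeights(randomConnectome(24, density = 0.5, seed = 200 + s))
    p <- permuteConnectome(g, seed = 300 + s)
    m <- wlAlign(g, p$connectome)
    expect_equal(nodeMatchingRatio(m, p$truth), 1)
  }
  expect_error(wlAlign(g, randomConnectome(10, seed = 1)), "same number")
})

test_that("depth-0 alignment reduces to optimal volume matching", {
  g1 <- randomConnectome(8, density = 0.7, seed = 61)
  g2 <- randomConnectome(8, density = 0.7, seed = 62)
  prm <- wlParams(8, depth = 0)
  m <- wlAlign(g1, g2, prm)
  # signatures are the volumes, so the optimal assignment cost equals
  # the 1-D optimal transport of sorted volumes
  v1 <- sort(unname(nodeVolume(g1)))
  v2 <- sort(unname(nodeVolume(g2)))
  expect_equal(attr(m, "totalCost"), sum(abs(v1 - v2)), tolerance = 1e-10)
})

test_that("deeper signature entries respect the contribution decay bound", {
  g <- randomConnectome(10, density = 0.8, seed = 77)
  prm <- wlParams(10, width = 2, depth = 2)
  S <- signatureTable(g, prm)
  maxVol <- max(nodeVolume(g))
  # each hop multiplies by w/vol <= 1: children of the root entry are
  # bounded by vol-ratio times the maximal volume
  expect_true(all(S[, 2:3] <= maxVol + 1e-12))
  expect_true(all(S[, 4:7] <= maxVol + 1e-12))
})

test_that("hemisphere-wise alignment recovers within-hemisphere permutations", {
  for (s in 1:3) {
    g <- normalizeWeights(randomConnectome(20, density = 0.6, seed = 400 + s,
                                           hemispheres = TRUE))
    p <- permuteConnectome(g, seed = 500 + s)
    m <- wlAlignHemispheres(g, p$connectome)
    expect_equal(nodeMatchingRatio(m, p$truth), 1)

    # never maps across hemispheres
    h <- hemisphereTags(g)
    mm <- alignmentMap(m)
    expect_true(all(h[names(mm)] == h[mm]))

    # restriction to L equals aligning the L subgraphs directly
    halves1 <- splitHemispheres(g)
    halves2 <- splitHemispheres(p$connectome)
    mL <- wlAlign(halves1$L, halves2$L,
                  wlParams(nNodes(halves1$L)))
    expect_equal(mm[nodeLabels(halves1$L)], alignmentMap(mL))
  }
  expect_error(wlAlignHemispheres(randomConnectome(6, seed = 1),
                                  randomConnectome(6, seed = 2)), "tag")
})
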
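test_that("nodeMatchingRatio counts agreements with the ground truth", {
  tgt <- letters[1:4]
  mStar <- Alignment(stats::setNames(tgt, LETTERS[1:4]), targetLabels = tgt)
  expect_equal(nodeMatchingRatio(mStar, mStar), 1)

  swapped <- Alignment(stats::setNames(tgt[c(2, 1, 4, 3)], LETTERS[1:4]),
                       targetLabels = tgt)
  expect_equal(nodeMatchingRatio(swapped, mStar), 0)

  half <- Alignment(stats::setNames(tgt[c(1, 2, 4, 3)], LETTERS[1:4]),
                    targetLabels = tgt)
  expect_equal(nodeMatchingRatio(half, mStar), 0.5)

  other <- Alignment(stats::setNames(tgt, c("P", "Q", "R", "S")),
                     targetLabels = tgt)
  expect_error(nodeMatchingRatio(other, mStar), "source")
})

test_that("alignment-quality metrics agree with their definitions", {
  g <- normalizeWeights(randomConnectome(10, density = 0.6, seed = 61))
  p <- permuteConnectome(g, seed = 62)

  expect_equal(jaccardOfAlignment(p$truth, g, p$connectome), 1)
  expect_equal(frobeniusOfAlignment(p$truth, g, p$connectome), 0)
  expect_equal(jaccardRatio(p$truth, p$truth, g, p$connectome), 1)

  # FRO is definitionally the Frobenius norm distance after relabelling
  m <- randomAlignment(nodeLabels(g), nodeLabels(p$connectome))
  expect_equal(frobeniusOfAlignment(m, g, p$connectome),
               normDistance(relabelConnectome(g, m), p$connectome))

  # J(m) is invariant under a common relabelling of both graphs
  q <- permuteConnectome(g, seed = 63)$truth
  gq <- applyAlignment(g, q)
  g2q <- applyAlignment(p$connectome, q)
  mq <- composeAlignments(composeAlignments(q, m), invertAlignment(q))
  expect_equal(jaccardOfAlignment(mq, gq, g2q),
               jaccardOfAlignment(m, g, p$connectome))
})

test_that("identity alignment on edge-disjoint graphs scores zero Jaccard", {
  wa <- matrix(0, 4, 4)
  wa[1, 2] <- wa[2, 1] <- 1
  wb <- matrix(0, 4, 4)
  wb[3, 4] <- wb[4, 3] <- 1
  ga <- Connectome(wa)
  gb <- Connectome(wb)
  id <- identityAlignment(nodeLabels(ga))
  expect_equal(jaccardOfAlignment(id, ga, gb), 0)
  expect_error(jaccardRatio(id, id, ga, gb), "zero")
})

test_that("evaluatePair bundles the single-metric operations", {
  g <- normalizeWeights(randomConnectome(12, density = 0.6, seed = 71))
  p <- permuteConnectome(g, seed = 72)
  m <- wlAlign(g, p$connectome)
  rec <- evaluatePair(g, p$connectome, m, p$truth)

  expect_equal(rec$nmr, 1)
  expect_equal(rec$j_ratio, 1)
  expect_equal(rec$fro, 0)
  expect_equal(rec$gji, jaccardOfAlignment(m, g, p$connectome))
  expect_equal(rec$cosine,
               cosineSimilarity(relabelConnectome(g, m), p$connectome))
  nm <- attr(rec, "nodeMatch")
  expect_true(all(nm))
  expect_named(nm, sourceLabels(m), ignore.order = TRUE)
})

test_that("a random alignment matches about 1/n of the nodes", {
  g <- normalizeWeights(randomConnectome(10, density = 0.6, seed = 81))
  p <- permuteConnectome(g, seed = 82)
  set.seed(83)
  nmrs <- replicate(200, nodeMatchingRatio(
    randomAlignment(nodeLabels(g), nodeLabels(g)), p$truth))
  expect_equal(mean(nmrs), 1 / 10, tolerance = 0.35)
})

test_that("cohortExperiment evaluates all unordered pairs incl. self-pairs", {
  # single subject: only the self-pair, which WL-align solves exactly
  cohort1 <- makeCohort(1, n = 12, noiseLevel = 0, seed = 91)
  res1 <- cohortExperiment(cohort1)
  expect_equal(res1$nPairs, 1L)
  expect_equal(unname(res1$means["nmr"]), 1)
  expect_equal(unname(res1$means["fro"]), 0)

  # five subjects -> 15 unordered pairs including self-pairs
  cohort5 <- makeCohort(5, n = 10, noiseLevel = 0.2, seed = 92)
  res5 <- cohortExperiment(cohort5)
  expect_equal(res5$nPairs, 15L)
  expect_equal(res5$nFailed, 0L)
  expect_equal(unname(res5$means["gji"]), mean(res5$records$gji))

  # the mean over identical records equals the record
  expect_equal(unname(res1$means["gji"]), res1$records$gji[1])
})

test_that("selfMatchingRate averages to the cohort mean matching ratio", {
  cohort <- makeCohort(3, n = 10, noiseLevel = 0.4, seed = 95)
  res <- cohortExperiment(cohort)
  rate <- selfMatchingRate(res)
  expect_true(all(rate >= 0 & rate <= 1))
  expect_equal(mean(rate), unname(res$means["nmr"]))
  expect_error(selfMatchingRate(list(nodeMatch = NULL)), "per-node")
})

test_that("aligner failures are recorded as NA, not dropped", {
  cohort <- makeCohort(2, n = 8, noiseLevel = 0.1, seed = 97)
  failing <- function(g1, g2) stop("always fails")
  res <- suppressWarnings(cohortExperiment(cohort, aligner = failing))
  expect_equal(res$nFailed, res$nPairs)
  expect_true(all(is.na(res$records$nmr)))
})

test_that("bruteForceAlignment finds exact optima and refuses large inputs", {
  g <- normalizeWeights(randomConnectome(6, density = 0.8, seed = 101))
  p <- permuteConnectome(g, seed = 102)
  best <- bruteForceAlignment(g, p$connectome, objective = "gji")
  expect_equal(attr(best, "objectiveValue"), 1)
  expect_equal(nodeMatchingRatio(best, p$truth), 1)

  # cost objective agrees with the Hungarian solution
  for (s in 1:5) {
    g1 <- randomConnectome(6, density = 0.9, seed = 110 + s)
    g2 <- randomConnectome(6, density = 0.9, seed = 120 + s)
    prm <- wlParams(6)
    bf <- bruteForceAlignment(g1, g2, objective = "wl-cost", params = prm)
    hung <- wlAlign(g1, g2, prm)
    expect_equal(attr(bf, "objectiveValue"), attr(hung, "totalCost"),
                 tolerance = 1e-10)
  }

  big <- randomConnectome(9, seed = 1)
  expect_error(bruteForceAlignment(big, big), "refused")
})

test_that("ground-truth-optimal pairs keep the Jaccard ratio within [0, 1]", {
  g <- normalizeWeights(randomConnectome(6, density = 0.9, seed = 131))
  noisy <- perturbWeights(g, 0.3, seed = 132)
  p <- permuteConnectome(noisy, seed = 133)
  # certify that the ground truth is GJI-optimal by exhaustion before
  # asserting the ratio bound
  best <- bruteForceAlignment(g, p$connectome, objective = "gji")
  jTruth <- jaccardOfAlignment(p$truth, g, p$connectome)
  if (abs(attr(best, "objectiveValue") - jTruth) < 1e-12) {
    m <- wlAlign(g, p$connectome)
    jr <- jaccardRatio(m, p$truth, g, p$connectome)
    expect_gte(jr, 0)
    expect_lte(jr, 1 + 1e-12)
  }
  succeed()
})
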
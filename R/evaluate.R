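#' Node matching ratio
#'
#' The fraction of source nodes that an alignment maps to the same
#' target as the ground-truth alignment:
#' \eqn{\mathrm{NMr}(m) = |\{u : m(u) = m^*(u)\}| / |V_1|}.
#'
#' @param m an \linkS4class{Alignment}.
#' @param mStar the ground-truth \linkS4class{Alignment}; same source
#'   label set as \code{m}.
#' @return numeric in \eqn{[0, 1]}.
#' @export
nodeMatchingRatio <- function(m, mStar) {
  src <- sourceLabels(m)
  if (!setequal(src, sourceLabels(mStar))) {
    stop("the two alignments have different source label sets")
  }
  mean(alignmentMap(m)[src] == alignmentMap(mStar)[src])
}

#' Graph Jaccard index achieved by an alignment
#'
#' \eqn{J(m) = J(m(G_1), G_2)}: the GJI between the first graph
#' relabelled through the alignment and the second graph.
#'
#' @param m a bijective \linkS4class{Alignment} from \code{g1}'s labels
#'   to \code{g2}'s labels.
#' @param g1,g2 \linkS4class{Connectome}s.
#' @return numeric in \eqn{[0, 1]}.
#' @export
jaccardOfAlignment <- function(m, g1, g2) {
  graphJaccard(relabelConnectome(g1, m), g2)
}

#' Jaccard ratio of an alignment
#'
#' \eqn{Jr(m) = J(m) / J(m^*)}: the alignment's GJI normalised by the
#' ground truth's, accounting for the intrinsic dissimilarity of the
#' pair. Equal to 1 when \eqn{m = m^*}; bounded by 1 whenever the
#' ground truth is GJI-optimal.
#'
#' @inheritParams jaccardOfAlignment
#' @param mStar the ground-truth \linkS4class{Alignment}; its own GJI
#'   must be positive.
#' @return non-negative numeric.
#' @export
jaccardRatio <- function(m, mStar, g1, g2) {
  jStar <- jaccardOfAlignment(mStar, g1, g2)
  if (jStar == 0) stop("ground-truth alignment has zero graph Jaccard index")
  jaccardOfAlignment(m, g1, g2) / jStar
}

#' Frobenius distance achieved by an alignment
#'
#' \eqn{\mathrm{FRO}(m) = \|\mathrm{Adj}(m(G_1)) - \mathrm{Adj}(G_2)\|_F};
#' lies in \eqn{[0, 2]} for weight-normalised connectomes.
#'
#' @inheritParams jaccardOfAlignment
#' @return non-negative numeric.
#' @export
frobeniusOfAlignment <- function(m, g1, g2) {
  normDistance(relabelConnectome(g1, m), g2, type = "frobenius")
}

#' Evaluate one aligned pair against its ground truth
#'
#' Computes the full set of alignment-quality metrics for a pair: node
#' matching ratio, graph Jaccard index, Jaccard ratio, Frobenius
#' distance and cosine similarity of the aligned adjacencies.
#'
#' @inheritParams jaccardRatio
#' @return one-row \code{data.frame} with columns \code{nmr},
#'   \code{gji}, \code{j_ratio}, \code{fro}, \code{cosine}, plus the
#'   per-node correctness indicators in attribute \code{"nodeMatch"}
#'   (named logical vector over the source labels).
#' @export
evaluatePair <- function(g1, g2, m, mStar) {
  g1m <- relabelConnectome(g1, m)
  src <- sourceLabels(m)
  match <- alignmentMap(m)[src] == alignmentMap(mStar)[src]
  names(match) <- src
  jStar <- jaccardOfAlignment(mStar, g1, g2)
  j <- graphJaccard(g1m, g2)
  rec <- data.frame(
    nmr = mean(match),
    gji = j,
    j_ratio = if (jStar > 0) j / jStar else NA_real_,
    fro = normDistance(g1m, g2, type = "frobenius"),
    cosine = cosineSimilarity(g1m, g2))
  attr(rec, "nodeMatch") <- match
  rec
}

#' Build a cohort of subjects with ground-truth permutations
#'
#' Convenience generator for evaluation experiments: draws one base
#' connectome per cohort, derives each subject as a multiplicatively
#' noisy copy, and pairs every subject with a randomly permuted version
#' plus the permutation's ground-truth alignment.
#'
#' @param nSubjects number of subjects.
#' @param n nodes per connectome.
#' @param noiseLevel between-subject multiplicative log-noise
#'   (0 = identical subjects).
#' @param density edge density of the base graph.
#' @param seed integer seed.
#' @param hemispheres logical, tag nodes with hemispheres.
#' @return list of subjects, each a list with elements \code{original},
#'   \code{permuted} and \code{truth} (the \linkS4class{Alignment} from
#'   original to permuted labels).
#' @export
makeCohort <- function(nSubjects, n, noiseLevel = 0.3, density = 0.6,
                       seed = 1L, hemispheres = FALSE) {
  base <- normalizeWeights(randomConnectome(
    n, density = density, seed = seed, hemispheres = hemispheres))
  lapply(seq_len(nSubjects), function(s) {
    orig <- if (noiseLevel > 0) {
      perturbWeights(base, noiseLevel, seed = seed + s)
    } else {
      base
    }
    p <- permuteConnectome(orig, seed = seed + 1000L + s)
    list(original = orig, permuted = p$connectome, truth = p$truth)
  })
}

#' Run an alignment experiment over a cohort
#'
#' Aligns every unordered pair of subjects, self-pairs included: pair
#' \eqn{(i, j)} aligns subject \eqn{i}'s original connectome against
#' subject \eqn{j}'s permuted one, so the self-pair is literally a
#' subject versus a randomly permuted version of itself. Each pair is
#' scored with \code{\link{evaluatePair}} against the known ground
#' truth, and cohort means are the arithmetic averages over all pairs.
#' Aligner failures are recorded as \code{NA} rows, not dropped
#' silently; means are taken over the successful pairs.
#'
#' @param cohort a cohort from \code{\link{makeCohort}} (or any list of
#'   \code{original}/\code{permuted}/\code{truth} triples sharing one
#'   label universe).
#' @param aligner function \code{(g1, g2) -> Alignment}; defaults to
#'   \code{\link{wlAlign}} (use \code{\link{wlAlignHemispheres}} for
#'   tagged cohorts).
#' @return list with \code{records} (a \code{data.frame} of per-pair
#'   metrics with columns \code{subject1}, \code{subject2}, \code{nmr},
#'   \code{gji}, \code{j_ratio}, \code{fro}, \code{cosine}),
#'   \code{means} (named numeric vector of cohort averages),
#'   \code{nodeMatch} (logical matrix, pairs x nodes, of per-node
#'   correctness), and \code{nPairs}/\code{nFailed}.
#' @export
cohortExperiment <- function(cohort, aligner = wlAlign) {
  nS <- length(cohort)
  pairs <- which(upper.tri(diag(nS), diag = TRUE), arr.ind = TRUE)
  labels <- sourceLabels(cohort[[1]]$truth)
  rows <- vector("list", nrow(pairs))
  nodeMatch <- matrix(NA, nrow(pairs), length(labels),
                      dimnames = list(NULL, labels))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    g1 <- cohort[[i]]$original
    g2 <- cohort[[j]]$permuted
    mStar <- cohort[[j]]$truth
    rec <- tryCatch({
      m <- aligner(g1, g2)
      evaluatePair(g1, g2, m, mStar)
    }, error = function(e) {
      warning("aligner failed on pair (", i, ", ", j, "): ",
              conditionMessage(e))
      data.frame(nmr = NA_real_, gji = NA_real_, j_ratio = NA_real_,
                 fro = NA_real_, cosine = NA_real_)
    })
    nm <- attr(rec, "nodeMatch")
    if (!is.null(nm)) nodeMatch[r, names(nm)] <- nm
    attr(rec, "nodeMatch") <- NULL
    rows[[r]] <- cbind(data.frame(subject1 = i, subject2 = j), rec)
  }
  records <- do.call(rbind, rows)
  metricCols <- c("nmr", "gji", "j_ratio", "fro", "cosine")
  means <- vapply(records[metricCols], mean, numeric(1), na.rm = TRUE)
  list(records = records,
       means = means,
       nodeMatch = nodeMatch,
       nPairs = nrow(records),
       nFailed = sum(is.na(records$nmr)))
}

#' Per-node self-matching rate
#'
#' For each node, the fraction of evaluated pairs in which it was
#' matched to its ground-truth counterpart. The mean rate over nodes
#' equals the cohort mean node matching ratio.
#'
#' @param experiment result of \code{\link{cohortExperiment}}.
#' @return named numeric vector of rates in \eqn{[0, 1]}.
#' @export
selfMatchingRate <- function(experiment) {
  nm <- experiment$nodeMatch
  if (is.null(nm) || nrow(nm) == 0L) stop("experiment has no per-node data")
  colMeans(nm, na.rm = TRUE)
}

#' Exact alignment by exhaustive permutation search
#'
#' Enumerates all bijections between the node sets (feasible only for
#' \eqn{n \le 8}; larger inputs are refused) and returns the optimum for
#' the chosen objective: maximal graph Jaccard index, or minimal total
#' WL signature-distance cost. Used as an independent oracle for
#' \code{\link{solveAssignment}} and to certify GJI-optimality of
#' ground truths in Jaccard-ratio analyses.
#'
#' @param g1,g2 \linkS4class{Connectome}s of equal size \eqn{\le 8}.
#' @param objective \code{"gji"} (maximise GJI) or \code{"wl-cost"}
#'   (minimise the WL signature assignment cost).
#' @param params WL parameters for \code{objective = "wl-cost"}.
#' @return the optimal \linkS4class{Alignment}, with the achieved
#'   objective value in attribute \code{"objectiveValue"}.
#' @export
bruteForceAlignment <- function(g1, g2, objective = c("gji", "wl-cost"),
                                params = NULL) {
  objective <- match.arg(objective)
  n <- nNodes(g1)
  if (nNodes(g2) != n) stop("graphs must have the same number of nodes")
  if (n > 8) {
    stop("exhaustive search refused for n = ", n,
         " (> 8): n! permutations is infeasible")
  }
  perms <- .allPermutations(n)
  lab1 <- nodeLabels(g1)
  lab2 <- nodeLabels(g2)
  if (objective == "gji") {
    A <- adjacency(g1)
    B <- adjacency(g2)
    ut <- upper.tri(A, diag = TRUE)
    best <- -Inf
    bestP <- NULL
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      # relabelling g1's node i as lab2[p[i]] pairs A[i, j] with B[p_i, p_j]
      B2 <- B[p, p, drop = FALSE]
      val <- sum(pmin(A[ut], B2[ut])) / sum(pmax(A[ut], B2[ut]))
      if (val > best) {
        best <- val
        bestP <- p
      }
    }
    a <- Alignment(stats::setNames(lab2[bestP], lab1), targetLabels = lab2)
    attr(a, "objectiveValue") <- best
    a
  } else {
    if (is.null(params)) params <- wlParams(n)
    cost <- bipartiteCost(signatureTable(g1, params),
                          signatureTable(g2, params))
    res <- .bruteForceAssignment(cost)
    a <- Alignment(stats::setNames(lab2[res$perm], lab1),
                   targetLabels = lab2)
    attr(a, "objectiveValue") <- res$cost
    a
  }
}

# all permutations of 1..n as an n! x n matrix
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- row + seq_len(nrow(sub))
    out[block, 1] <- i
    out[block, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# exhaustive minimum of an assignment cost matrix (square, n <= 8)
.bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  if (n > 8) stop("exhaustive assignment refused for n > 8")
  perms <- .allPermutations(n)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  best <- which.min(totals)
  list(perm = perms[best, ], cost = totals[best])
}
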
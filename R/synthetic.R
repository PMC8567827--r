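#' Generate a random weighted connectome
#'
#' Draws a symmetric, non-negative, zero-diagonal weighted graph and, if
#' needed, adds bridging edges so the result is connected. Continuous
#' weight models (\code{"lognormal"}, \code{"uniform"}) produce almost
#' surely distinct weights, which keeps all WL expansion rankings strict;
#' the integer \code{"streamline"} model mimics raw streamline counts
#' and deliberately produces ties, for stress-testing tie handling.
#'
#' @param n number of nodes (\eqn{\ge 2}).
#' @param density probability of each possible edge, in \eqn{(0, 1]}.
#' @param weightModel \code{"lognormal"} (log-sd 1, the default — edge
#'   strengths spanning orders of magnitude, as streamline counts do),
#'   \code{"uniform"} on \eqn{(0, 1)}, or \code{"streamline"} (positive
#'   integers, negative-binomial shaped).
#' @param seed integer seed; the generator is fully deterministic
#'   given it.
#' @param hemispheres logical; when \code{TRUE} the first
#'   \eqn{\lceil n/2 \rceil} nodes are tagged \code{"L"} and the rest
#'   \code{"R"}.
#' @param interDensity edge probability across hemispheres (defaults to
#'   \code{density}); only used when \code{hemispheres = TRUE}.
#' @return a connected \linkS4class{Connectome} with labels
#'   \code{"n001"}, \code{"n002"}, ...
#' @export
randomConnectome <- function(n, density = 0.6,
                             weightModel = c("lognormal", "uniform",
                                             "streamline"),
                             seed = 1L, hemispheres = FALSE,
                             interDensity = density) {
  weightModel <- match.arg(weightModel)
  if (n < 2) stop("'n' must be >= 2")
  if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
  labels <- sprintf("n%03d", seq_len(n))
  hemi <- NULL
  if (hemispheres) {
    hemi <- stats::setNames(
      rep(c("L", "R"), c(ceiling(n / 2), floor(n / 2))), labels)
  }
  withr::with_seed(as.integer(seed), {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    p <- rep(density, nrow(ut))
    if (hemispheres) {
      cross <- hemi[ut[, 1]] != hemi[ut[, 2]]
      p[cross] <- interDensity
    }
    on <- stats::runif(nrow(ut)) < p
    m <- sum(on)
    wts <- switch(weightModel,
      lognormal = stats::rlnorm(m, meanlog = 0, sdlog = 1),
      uniform = stats::runif(m),
      streamline = stats::rnbinom(m, size = 2, mu = 30) + 1)
    w[ut[on, , drop = FALSE]] <- wts
    w <- w + t(w)
    dimnames(w) <- list(labels, labels)
    # connect components with bridging edges of a freshly drawn weight
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      w > 0, mode = "undirected"))
    if (comp$no > 1) {
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1], integer(1))
      for (k in seq_len(comp$no - 1)) {
        bw <- switch(weightModel,
          lognormal = stats::rlnorm(1, 0, 1),
          uniform = stats::runif(1),
          streamline = stats::rnbinom(1, size = 2, mu = 30) + 1)
        w[reps[k], reps[k + 1]] <- bw
        w[reps[k + 1], reps[k]] <- bw
      }
    }
    Connectome(w, labels = labels, hemisphere = hemi)
  })
}

#' Randomly permute the node labels of a connectome
#'
#' Draws a random permutation of the node labels, keeping track of it
#' as a ground-truth alignment \eqn{m^*}: applying \eqn{m^*} to the
#' permuted graph (\code{\link{applyAlignment}}) reproduces the original
#' exactly. When the connectome carries hemisphere tags, the
#' permutation acts within each hemisphere only, so per-hemisphere
#' evaluation designs stay consistent.
#'
#' @param g a \linkS4class{Connectome}.
#' @param seed integer seed.
#' @return list with elements \code{connectome} (the relabelled graph,
#'   same label set) and \code{truth} (the \linkS4class{Alignment} from
#'   the original graph's labels to the permuted graph's labels).
#' @export
permuteConnectome <- function(g, seed = 1L) {
  n <- nNodes(g)
  lab <- nodeLabels(g)
  h <- hemisphereTags(g)
  sigma <- withr::with_seed(as.integer(seed), {
    if (length(h) == n) {
      s <- seq_len(n)
      for (side in c("L", "R")) {
        idx <- which(h == side)
        s[idx] <- idx[sample.int(length(idx))]
      }
      s
    } else {
      sample.int(n)
    }
  })
  # node i of the original becomes the node labelled lab[sigma[i]]
  w <- adjacency(g)
  wp <- matrix(0, n, n, dimnames = list(lab, lab))
  wp[sigma, sigma] <- w
  gp <- Connectome(wp, labels = lab,
                   hemisphere = if (length(h) == n) h)
  truth <- Alignment(stats::setNames(lab[sigma], lab), targetLabels = lab)
  list(connectome = gp, truth = truth)
}

#' Perturb edge weights with multiplicative noise
#'
#' Applies i.i.d. lognormal multiplicative noise (log-sd =
#' \code{noiseLevel}) to every existing edge and renormalises the total
#' unique-edge weight to 1. Multiplicative noise respects the
#' positivity and the orders-of-magnitude spread of connectome weights;
#' the zero pattern (topology) is preserved, and \code{noiseLevel = 0}
#' returns the weight-normalised graph unchanged up to normalisation.
#'
#' @param g a \linkS4class{Connectome}.
#' @param noiseLevel non-negative standard deviation of the log-noise.
#' @param seed integer seed.
#' @return a weight-normalised \linkS4class{Connectome} with the same
#'   topology.
#' @export
perturbWeights <- function(g, noiseLevel, seed = 1L) {
  if (noiseLevel < 0) stop("'noiseLevel' must be >= 0")
  w <- adjacency(g)
  ut <- which(upper.tri(w) & w > 0)
  withr::with_seed(as.integer(seed), {
    noise <- stats::rlnorm(length(ut), meanlog = 0, sdlog = noiseLevel)
    w[ut] <- w[ut] * noise
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    normalizeWeights(.withWeights(g, w))
  })
}

#' Generate a multi-resolution cohort of connectomes
#'
#' Emulates a cohort observed through atlases of different granularity.
#' One latent fine-grained weighted graph is drawn per cohort; each
#' subject differs from it through multiplicative per-node strength
#' factors (structural differences that are spatially coherent, so they
#' survive parcel aggregation) and through finite tractography sampling:
#' a fixed total streamline budget is distributed over the latent edges
#' by Poisson counting. Every requested resolution then aggregates the
#' subject's latent counts by summing within parcel blocks (latent
#' nodes partitioned into contiguous, as-even-as-possible parcels) and
#' normalises the weights.
#'
#' This reproduces the two resolution effects seen in real connectome
#' cohorts: finer parcellations spread the same total connectivity over
#' quadratically more, smaller entries (so the absolute Frobenius
#' distance between subjects falls as the parcel count grows), while
#' the per-entry streamline counts shrink and their relative sampling
#' noise grows (so the graph Jaccard index between subjects falls too —
#' the inverted trend between the two measures).
#'
#' @param nSubjects number of subjects.
#' @param resolutions integer vector of parcel counts, each
#'   \eqn{\le} \code{latentNodes}.
#' @param latentNodes size of the latent fine-grained graph (default
#'   600).
#' @param noiseLevel log-sd of the per-subject node strength factors
#'   (default 0.3).
#' @param density latent edge density (default 0.3).
#' @param totalStreamlines streamline budget per subject (default
#'   2e5, a desk-scale stand-in for whole-brain tractography budgets).
#' @param seed integer seed.
#' @return named list, one element per resolution (names are the parcel
#'   counts), each a list of \code{nSubjects} weight-normalised
#'   \linkS4class{Connectome}s on labels \code{"p001"}, ...
#' @export
multiresolutionCohort <- function(nSubjects, resolutions, latentNodes = 600,
                                  noiseLevel = 0.3, density = 0.3,
                                  totalStreamlines = 2e5, seed = 1L) {
  if (any(resolutions > latentNodes)) {
    stop("resolutions must not exceed the latent node count")
  }
  template <- randomConnectome(latentNodes, density = density,
                               weightModel = "lognormal", seed = seed)
  wT <- adjacency(template)
  ut <- which(upper.tri(wT))
  subjects <- lapply(seq_len(nSubjects), function(s) {
    withr::with_seed(as.integer(seed) + s, {
      f <- stats::rlnorm(latentNodes, 0, noiseLevel)
      ws <- wT * outer(f, f)
      lambda <- ws[ut] / sum(ws[ut]) * totalStreamlines
      cts <- matrix(0, latentNodes, latentNodes)
      cts[ut] <- stats::rpois(length(ut), lambda)
      cts + t(cts)
    })
  })
  out <- lapply(resolutions, function(r) {
    # contiguous, as-even-as-possible partition of latent nodes
    parcel <- sort(rep_len(seq_len(r), latentNodes))
    M <- matrix(0, latentNodes, r)
    M[cbind(seq_len(latentNodes), parcel)] <- 1
    lapply(subjects, function(cts) {
      w <- t(M) %*% cts %*% M
      diag(w) <- 0
      normalizeWeights(Connectome(w, labels = sprintf("p%03d", seq_len(r))))
    })
  })
  names(out) <- as.character(resolutions)
  out
}

#' Example pair of sets for the Jaccard index
#'
#' Two integer sets with an intersection of 3 elements and a union of
#' 33, so their Jaccard similarity is \eqn{3/33 \approx 0.09}.
#'
#' @return list with elements \code{a} and \code{b}.
#' @export
jaccardExampleSets <- function() {
  list(a = 1:18, b = 16:33)
}

#' Example graph for the WL signature expansion
#'
#' An 8-node two-level star: a centre \code{u} with two neighbours
#' \code{v1}, \code{v2}, which in turn lead to leaves \code{w1..w3} and
#' \code{w4, w5}. The concrete weights are chosen so that every top-k
#' ranking in the width-2, depth-2 expansion is strict, which makes the
#' 7-entry signature of \code{u} computable in closed form: the
#' expansion visits \code{u}; then \code{v1}, \code{v2}; then from
#' \code{v1} the back-path to \code{u} and \code{w1}, and from \code{v2}
#' the leaves \code{w4} and \code{w5}.
#'
#' @return a \linkS4class{Connectome} on labels
#'   \code{u, v1, v2, w1..w5}.
#' @export
signatureExampleGraph <- function() {
  lab <- c("u", "v1", "v2", "w1", "w2", "w3", "w4", "w5")
  w <- matrix(0, 8, 8, dimnames = list(lab, lab))
  w["u", "v1"] <- 4    # a1
  w["u", "v2"] <- 1    # a2
  w["v1", "w1"] <- 1.0 # b1
  w["v1", "w2"] <- 0.9 # b2
  w["v1", "w3"] <- 0.8 # b3
  w["v2", "w4"] <- 3   # b4
  w["v2", "w5"] <- 2.5 # b5
  w <- w + t(w)
  Connectome(w, labels = lab)
}
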
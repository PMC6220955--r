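## Cluster-based permutation test on sensor topographies (paired design,
## within-subject sign flips, maximum-cluster-statistic correction).

## connected components of `nodes` (integer indices) under adjacency list
connectedComponents <- function(nodes, adjacency) {
  comps <- list()
  remaining <- nodes
  while (length(remaining) > 0L) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      if (!v %in% comp) {
        comp <- c(comp, v)
        nb <- intersect(adjacency[[v]], remaining)
        queue <- c(queue, setdiff(nb, comp))
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

## signed clusters of one t-topography: list(sign, members, stat)
.tClusters <- function(tvals, crit, adjacency) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvals > crit)
    if (length(supra) == 0L) next
    for (comp in connectedComponents(supra, adjacency))
      out[[length(out) + 1L]] <- list(sign = sgn, members = comp,
                                      stat = sum(tvals[comp]))
  }
  out
}

#' Cluster-based permutation test for paired sensor topographies
#'
#' Compares two within-subject topographies (e.g. attend-left vs
#' attend-right alpha power). Channels with a paired t-value beyond the
#' two-tailed `clusterAlpha` threshold are clustered by spatial adjacency
#' (Delaunay triangulation of the planar-projected montage); the cluster
#' statistic is the sum of t-values. The null distribution of the most
#' extreme cluster statistic is built from random within-subject sign
#' flips of the condition difference, and cluster p-values are corrected
#' for two-sided testing by doubling (capped at 1).
#'
#' @param topoA,topoB subjects x channels matrices
#' @param montage a [Montage-class] matching the channel columns
#' @param nPerm number of random permutations (default 1000)
#' @param clusterAlpha channel-level threshold, two-tailed (default 0.05)
#' @param seed integer RNG seed
#' @return a [ClusterTestResult-class]
#' @export
clusterPermutationTest <- function(topoA, topoB, montage, nPerm = 1000L,
                                   clusterAlpha = 0.05, seed = 1L) {
  stopifnot(all(dim(topoA) == dim(topoB)))
  n <- nrow(topoA)
  nCh <- ncol(topoA)
  if (n < 6) stop("at least 6 subjects required")
  if (nCh != length(montage@labels))
    stop("column count must match the montage")
  nb <- montageNeighbours(montage)
  adjacency <- nb$adjacency
  if (any(lengths(adjacency) == 0L))
    warning("montage neighbour graph is disconnected; clusters limited ",
            "to connected components")
  D <- topoA - topoB
  crit <- qt(1 - clusterAlpha / 2, df = n - 1)
  ssq <- colSums(D^2)

  tFromMean <- function(m) {
    v <- (ssq - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  tObs <- tFromMean(colMeans(D))
  obs <- .tClusters(tObs, crit, adjacency)

  ## permutation null of the most extreme cluster statistic per sign;
  ## t-values for all sign flips in one matrix product
  withSeed(seed, {
    S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    M <- (S %*% D) / n
    V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
    Tp <- M / sqrt(pmax(V, .Machine$double.eps) / n)
    nullPos <- numeric(nPerm)
    nullNeg <- numeric(nPerm)
    anySupra <- rowSums(abs(Tp) > crit) > 0L
    for (b in which(anySupra)) {
      cl <- .tClusters(Tp[b, ], crit, adjacency)
      if (length(cl)) {
        stats <- vapply(cl, `[[`, 0, "stat")
        nullPos[b] <- max(c(stats[stats > 0], 0))
        nullNeg[b] <- min(c(stats[stats < 0], 0))
      }
    }
  })
  if (length(obs) == 0L) {
    clusters <- data.frame(id = integer(0), sign = integer(0),
                           nChannels = integer(0), stat = numeric(0),
                           p = numeric(0))
    members <- list()
  } else {
    clusters <- do.call(rbind, lapply(seq_along(obs), function(i) {
      cl <- obs[[i]]
      p1 <- if (cl$sign > 0)
        (1 + sum(nullPos >= cl$stat)) / (nPerm + 1)
      else
        (1 + sum(nullNeg <= cl$stat)) / (nPerm + 1)
      data.frame(id = i, sign = cl$sign, nChannels = length(cl$members),
                 stat = cl$stat, p = min(1, 2 * p1))
    }))
    members <- lapply(obs, function(cl) montage@labels[cl$members])
  }
  new("ClusterTestResult", clusters = clusters, members = members,
      nPerm = as.integer(nPerm), neighborMeanDegree = nb$meanDegree)
}

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult: %d cluster(s), %d permutations, mean degree %.1f\n",
    nrow(object@clusters), object@nPerm, object@neighborMeanDegree))
  if (nrow(object@clusters)) print(object@clusters)
})
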
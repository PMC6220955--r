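## Electrode montage construction, azimuthal projection and the
## triangulation-based channel neighbour graph used by the cluster test.

#' Construct a symmetric spherical electrode montage
#'
#' Places `nChannels` electrodes on concentric rings of a unit sphere in a
#' layout mirror-symmetric about the sagittal plane (extended 10-20 style
#' coverage down-sampled to the requested count) and defines two laterally
#' symmetric parieto-occipital analysis clusters.
#'
#' @param nChannels total electrode count (>= 16 recommended; default 32)
#' @param clusterSize electrodes per parieto-occipital cluster
#'   (default `max(2, round(nChannels / 8))`)
#' @return a [Montage-class]
#' @examples
#' m <- makeMontage(32)
#' leftCluster(m)
#' @export
makeMontage <- function(nChannels = 32,
                        clusterSize = max(2L, round(nChannels / 8))) {
  if (nChannels < 8) stop("at least 8 channels required")
  ## rings from vertex (0 deg) to just below the equator (105 deg);
  ## ring capacity proportional to sin(theta)
  nRings <- max(3L, round(sqrt(nChannels)))
  theta <- seq(0, 105, length.out = nRings + 1L)[-1L] * pi / 180
  w <- sin(theta) / sum(sin(theta))
  counts <- pmax(2L, round(w * (nChannels - 1L)))
  ## adjust to hit the exact total (vertex channel + rings)
  while (sum(counts) + 1L != nChannels) {
    i <- which.max(counts)
    if (sum(counts) + 1L > nChannels) counts[i] <- counts[i] - 1L
    else counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  }
  pos <- matrix(c(0, 0, 1), nrow = 1)
  for (k in seq_along(theta)) {
    nk <- counts[k]
    ## half-offset azimuths: the set is closed under phi -> -phi
    phi <- ((seq_len(nk) - 0.5) * 2 * pi / nk) - pi
    pos <- rbind(pos, cbind(sin(theta[k]) * sin(phi),
                            sin(theta[k]) * cos(phi),
                            cos(theta[k])))
  }
  labels <- sprintf("ch%02d", seq_len(nrow(pos)))
  ## parieto-occipital cluster seeds (left/right mirror directions)
  seedL <- c(-0.45, -0.75, 0.49); seedL <- seedL / sqrt(sum(seedL^2))
  seedR <- c(0.45, -0.75, 0.49); seedR <- seedR / sqrt(sum(seedR^2))
  dL <- angDist(pos, seedL)
  dR <- angDist(pos, seedR)
  left <- labels[order(dL)[seq_len(clusterSize)]]
  right <- labels[order(dR)[seq_len(clusterSize)]]
  if (length(intersect(left, right)) > 0L)
    stop("clusterSize too large: clusters overlap at the midline")
  new("Montage", labels = labels, positions = pos,
      leftCluster = left, rightCluster = right)
}

#' @describeIn makeMontage labels of the left parieto-occipital cluster
#' @param montage a [Montage-class]
#' @export
leftCluster <- function(montage) montage@leftCluster

#' @describeIn makeMontage labels of the right parieto-occipital cluster
#' @export
rightCluster <- function(montage) montage@rightCluster

#' @describeIn makeMontage channel labels
#' @export
channelLabels <- function(montage) montage@labels

#' @describeIn makeMontage n x 3 matrix of unit-sphere positions
#' @export
channelPositions <- function(montage) montage@positions

setMethod("show", "Montage", function(object) {
  cat(sprintf(
    "Montage: %d channels, clusters %d (L) / %d (R)\n",
    length(object@labels), length(object@leftCluster),
    length(object@rightCluster)))
})

#' Azimuthal equidistant (planar) projection of electrode positions
#'
#' Projects unit-sphere positions to the plane with the vertex at the
#' origin and planar radius equal to the polar angle, preserving angular
#' distance from the vertex; this is the planar layout on which channel
#' neighbourhoods are triangulated.
#'
#' @param montage a [Montage-class]
#' @return n x 2 matrix of planar coordinates
#' @export
projectAzimuthal <- function(montage) {
  p <- montage@positions
  thetaPol <- acos(pmin(1, pmax(-1, p[, 3])))
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  fac <- ifelse(rho > 1e-12, thetaPol / rho, 0)
  cbind(p[, 1] * fac, p[, 2] * fac)
}

#' Channel neighbour graph from Delaunay triangulation
#'
#' Builds the neighbour structure of the montage by Delaunay-triangulating
#' the planar (azimuthal) projection of the 3-D electrode positions; two
#' channels are neighbours when the triangulation connects them. Long
#' edges (beyond `maxEdgeFactor` times the median edge length) are pruned
#' to avoid spurious neighbours across the montage rim.
#'
#' @param montage a [Montage-class]
#' @param maxEdgeFactor pruning factor for rim-spanning edges (default 2.5)
#' @return list with `adjacency` (list of integer neighbour indices per
#'   channel) and `meanDegree`
#' @export
montageNeighbours <- function(montage, maxEdgeFactor = 2.5) {
  xy <- projectAzimuthal(montage)
  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  keep <- len <= maxEdgeFactor * stats::median(len)
  seg <- seg[keep, , drop = FALSE]
  n <- nrow(xy)
  adj <- vector("list", n)
  for (i in seq_len(nrow(seg))) {
    a <- seg$ind1[i]; b <- seg$ind2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  list(adjacency = adj, meanDegree = mean(lengths(adj)))
}
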
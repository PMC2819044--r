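# Voronoi zones of influence, geodesic zone centers, Delaunay triangulation
# and the mean inter-nuclear edge length (parameter V and the edge e).

#' Voronoi zones of influence of the nuclei
#'
#' Partitions the ROI into per-nucleus zones of influence: each ROI pixel is
#' assigned to the nucleus at minimum geodesic (within-ROI, 8-neighbour
#' chessboard) distance, by multi-source distance propagation from the
#' nucleus pixels. Equidistant (SKIZ boundary) pixels go to the lower
#' nucleus label, so the zones are a deterministic exact partition of the
#' ROI. The mean zone area is the cytoplasm proxy V = A / count.
#'
#' @param nuclei a [NucleiLabelMap-class] with `count >= 1`.
#' @param roi logical ROI mask.
#' @return an [InfluenceMap-class].
#' @export
influenceZones <- function(nuclei, roi) {
  stopifnot(is(nuclei, "NucleiLabelMap"))
  if (nuclei@count < 1) stop("influence zones require at least one nucleus")
  stopifnot(all(dim(nuclei@labels) == dim(roi)))
  roi <- matrix(as.logical(roi), nrow(roi), ncol(roi))
  zones <- cpp_influence_zones(nuclei@labels, roi)
  if (any(zones[roi] == 0))
    warning("ROI pixels unreachable from any nucleus remain unassigned ",
            "(disconnected ROI component without nuclei)")
  new("InfluenceMap", zones = zones,
      meanZoneArea = sum(roi) / nuclei@count)
}

#' Geodesic centers of the zones of influence
#'
#' For every zone, the zone pixel minimising the maximum within-zone
#' geodesic distance to all pixels of the zone (the geodesic center, a
#' point guaranteed to lie inside the zone even when the zone is concave,
#' unlike the Euclidean centroid). The chessboard metric produces plateaus
#' of equal eccentricity, so ties are broken by maximal geodesic depth
#' (the most interior plateau pixel) and then by smallest (row, col).
#'
#' @param zones an [InfluenceMap-class] (or an integer label matrix).
#' @return n x 2 matrix of (row, col) centers, one row per zone.
#' @export
geodesicCenters <- function(zones) {
  z <- if (is(zones, "InfluenceMap")) zones@zones else zones
  n <- max(z, 0)
  if (n < 1) return(matrix(numeric(0), 0, 2))
  ctr <- cpp_geodesic_centers(z, as.integer(n))
  colnames(ctr) <- c("row", "col")
  ctr
}

#' Delaunay triangulation of zone centers with ROI pruning
#'
#' Delaunay triangulation of the center points; edges whose straight
#' segment leaves the ROI are discarded (they are false neighbour relations
#' across concavities of the epithelium). The mean edge length is computed
#' over the retained unique edges (`edgeMode = "unique"`, default) or over
#' all triangle edges with multiplicity (`edgeMode = "triangle"`).
#'
#' Two points give the single connecting edge; collinear point sets give
#' the chain of consecutive edges, flagged degenerate.
#'
#' @param points n x 2 matrix of (row, col) coordinates.
#' @param roi optional logical ROI mask used to prune edges.
#' @param edgeMode `"unique"` or `"triangle"`.
#' @return a [Triangulation-class].
#' @export
delaunayTriangulation <- function(points, roi = NULL,
                                  edgeMode = c("unique", "triangle")) {
  edgeMode <- match.arg(edgeMode)
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  n <- nrow(points)
  if (n == 0)
    return(new("Triangulation", points = points,
      edges = matrix(integer(0), 0, 2), meanEdgeLength = NA_real_,
      degenerate = FALSE))
  if (n == 1)
    return(new("Triangulation", points = points,
      edges = matrix(integer(0), 0, 2), meanEdgeLength = NA_real_,
      degenerate = FALSE))

  collinear <- n == 2 || .allCollinear(points)
  if (collinear) {
    o <- .chainOrder(points)
    edges <- cbind(o[-n], o[-1])
    tris <- matrix(integer(0), 0, 3)
    if (n > 2) warning("all points collinear; returning chain edges")
  } else {
    tris <- .bowyerWatson(points)
    edges <- unique(rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)]))
  }
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges, MARGIN = 1)
  if (!is.null(roi))
    edges <- edges[.edgeInsideRoi(points, edges, roi), , drop = FALSE]
  len <- sqrt((points[edges[, 1], 1] - points[edges[, 2], 1])^2 +
              (points[edges[, 1], 2] - points[edges[, 2], 2])^2)
  meanEdge <- if (edgeMode == "unique" || nrow(tris) == 0) {
    if (length(len)) mean(len) else NA_real_
  } else {
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    te <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)])
    te <- cbind(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2]))
    tkey <- paste(te[, 1], te[, 2])
    tlen <- sqrt((points[te[, 1], 1] - points[te[, 2], 1])^2 +
                 (points[te[, 1], 2] - points[te[, 2], 2])^2)
    keep <- tkey %in% key
    if (any(keep)) mean(tlen[keep]) else NA_real_
  }
  new("Triangulation", points = points,
      edges = matrix(as.integer(edges), ncol = 2),
      meanEdgeLength = meanEdge, degenerate = collinear && n > 2)
}

.allCollinear <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  length(sv) < 2 || sv[2] < 0.5
}

.chainOrder <- function(points) {
  ctr <- sweep(points, 2, colMeans(points))
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  order(ctr %*% v)
}

# does the straight segment between the two endpoints stay inside the ROI?
.edgeInsideRoi <- function(points, edges, roi) {
  if (nrow(edges) == 0) return(logical(0))
  vapply(seq_len(nrow(edges)), function(i) {
    p <- points[edges[i, 1], ]
    q <- points[edges[i, 2], ]
    len <- sqrt(sum((p - q)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(2 * len)))
    r <- pmin(nrow(roi), pmax(1, round(p[1] + t * (q[1] - p[1]))))
    cc <- pmin(ncol(roi), pmax(1, round(p[2] + t * (q[2] - p[2]))))
    all(roi[cbind(r, cc)])
  }, logical(1))
}

# Bowyer-Watson incremental Delaunay triangulation. A deterministic 1e-6
# jitter breaks the cocircular degeneracies of integer pixel grids; it is
# used only for the incircle tests, never for the returned geometry.
.bowyerWatson <- function(points) {
  n <- nrow(points)
  i <- seq_len(n)
  px <- points[, 2] + ((i * 0.618033988749895) %% 1 - 0.5) * 1e-6
  py <- points[, 1] + ((i * 0.754877666246693) %% 1 - 0.5) * 1e-6
  cx <- mean(range(px)); cy <- mean(range(py))
  R <- max(diff(range(px)), diff(range(py)), 1) * 16
  px <- c(px, cx - 2 * R, cx + 2 * R, cx)
  py <- c(py, cy - R, cy - R, cy + 2 * R)

  circum <- function(a, b, c) {
    d <- 2 * (px[a] * (py[b] - py[c]) + px[b] * (py[c] - py[a]) +
              px[c] * (py[a] - py[b]))
    aa <- px[a]^2 + py[a]^2; bb <- px[b]^2 + py[b]^2; cc <- px[c]^2 + py[c]^2
    ux <- (aa * (py[b] - py[c]) + bb * (py[c] - py[a]) +
           cc * (py[a] - py[b])) / d
    uy <- (aa * (px[c] - px[b]) + bb * (px[a] - px[c]) +
           cc * (px[b] - px[a])) / d
    cbind(ux, uy, (px[a] - ux)^2 + (py[a] - uy)^2)
  }

  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- circum(tri[, 1], tri[, 2], tri[, 3])
  for (ip in seq_len(n)) {
    bad <- (px[ip] - cc[, 1])^2 + (py[ip] - cc[, 2])^2 < cc[, 3]
    if (!any(bad)) next  # cannot happen inside the super-triangle
    bt <- tri[bad, , drop = FALSE]
    be <- rbind(bt[, 1:2], bt[, 2:3], bt[, c(1, 3)])
    be <- cbind(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))
    key <- be[, 1] * (n + 4) + be[, 2]
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    boundary <- be[!dup, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(boundary) > 0) {
      newt <- cbind(boundary, ip)
      tri <- rbind(tri, newt)
      cc <- rbind(cc, circum(newt[, 1], newt[, 2], newt[, 3]))
    }
  }
  keep <- apply(tri <= n, 1, all)
  matrix(as.integer(tri[keep, , drop = FALSE]), ncol = 3)
}
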
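# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive and separate from the
# package's own algorithms.

# exhaustive nearest-nucleus search under the chessboard metric (valid as a
# geodesic oracle on rectangular full-frame ROIs), ties to the lowest label
bruteVoronoi <- function(labels, roi) {
  nuc <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[nuc]
  out <- matrix(0L, nrow(labels), ncol(labels))
  pix <- which(roi, arr.ind = TRUE)
  d <- pmax(abs(outer(pix[, 1], nuc[, 1], "-")),
            abs(outer(pix[, 2], nuc[, 2], "-")))
  for (i in seq_len(nrow(pix))) {
    di <- d[i, ]
    out[pix[i, 1], pix[i, 2]] <- min(lab[di == min(di)])
  }
  out
}

# exhaustive geodesic-center search: BFS from every pixel of the region,
# minimise the maximum distance, ties by maximal depth then smallest
# (row, col)
bruteGeodesicCenter <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  n <- nrow(pix)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[pix] <- seq_len(n)
  adj <- lapply(seq_len(n), function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
    nb <- nb[nb$r >= 1 & nb$r <= nrow(mask) &
             nb$c >= 1 & nb$c <= ncol(mask), ]
    v <- idx[cbind(nb$r, nb$c)]
    v[v > 0 & v != i]
  })
  ecc <- vapply(seq_len(n), function(s) {
    d <- rep(-1L, n); d[s] <- 0L; q <- s; head <- 1
    while (head <= length(q)) {
      u <- q[head]; head <- head + 1
      for (v in adj[[u]]) if (d[v] < 0) { d[v] <- d[u] + 1L; q <- c(q, v) }
    }
    max(d)
  }, integer(1))
  # geodesic depth: BFS inward from the boundary pixels
  deg <- lengths(adj)
  depth <- rep(0L, n)
  q <- which(deg < 8)
  depth[q] <- 1L
  head <- 1
  while (head <= length(q)) {
    u <- q[head]; head <- head + 1
    for (v in adj[[u]]) if (depth[v] == 0) {
      depth[v] <- depth[u] + 1L; q <- c(q, v)
    }
  }
  best <- which(ecc == min(ecc))
  best <- best[order(-depth[best], pix[best, 1], pix[best, 2])][1]
  pix[best, ]
}

# squared circumcircle test: is any non-vertex point strictly inside a
# triangle's circumcircle?
circumcircleViolated <- function(pts, tris, tol = 1e-9) {
  for (i in seq_len(nrow(tris))) {
    a <- pts[tris[i, 1], ]; b <- pts[tris[i, 2], ]; c <- pts[tris[i, 3], ]
    ax <- a[2]; ay <- a[1]; bx <- b[2]; by <- b[1]; cx <- c[2]; cy <- c[1]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(nrow(pts)), tris[i, ])
    if (any((pts[others, 2] - ux)^2 + (pts[others, 1] - uy)^2 <
            r2 * (1 - tol))) return(TRUE)
  }
  FALSE
}

# place discrete discs of the given radius at (row, col) centers
discImage <- function(height, width, centers, radius = 8,
                      fg = 0, bg = 255) {
  grey <- matrix(bg, height, width)
  off <- which(outer((-radius:radius)^2, (-radius:radius)^2, "+") <=
               radius^2, arr.ind = TRUE) - radius - 1
  for (i in seq_len(nrow(centers)))
    grey[cbind(off[, 1] + centers[i, 1], off[, 2] + centers[i, 2])] <- fg
  grey
}

# wrap a grey matrix into an EpitheliumImage with full-frame ROI
asImage <- function(grey, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(grey), ncol(grey))
  new("EpitheliumImage", grey = grey, roi = roi,
      pixelArea = defaultPixelArea())
}

# labelled map from a binary mask (bypasses segmentation)
asNuclei <- function(mask) {
  lab <- labelComponents(mask)
  n <- max(lab)
  new("NucleiLabelMap", labels = lab, count = as.integer(n),
      meanArea = if (n > 0) sum(lab > 0) / n else NA_real_)
}

# random blobby binary mask for property tests
randomMask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w)

# minimum Euclidean border-to-border distance between two labelled
# components
minComponentGap <- function(lab, a, b) {
  pa <- which(lab == a, arr.ind = TRUE)
  pb <- which(lab == b, arr.ind = TRUE)
  min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}
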
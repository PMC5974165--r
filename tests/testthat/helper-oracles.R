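# Independent brute-force oracles used to validate the package's
# implementations. Each is written from the definition, not from the code
# path it checks.

# AUC as an explicit pairwise win count (ties worth one half).
oracle_auc <- function(presence, background) {
  wins <- 0
  for (p in presence) {
    for (b in background) {
      wins <- wins + (p > b) + 0.5 * (p == b)
    }
  }
  wins / (length(presence) * length(background))
}

# Equal sensitivity-specificity threshold by exhaustive scan of the observed
# values, smallest candidate on ties.
oracle_threshold <- function(presence, background) {
  cand <- sort(unique(c(presence, background)))
  gaps <- sapply(cand, function(t) {
    abs(mean(presence >= t) - mean(background < t))
  })
  cand[which(gaps == min(gaps))[1]]
}

# Convex hull vertex set by the O(n^3) definition: a point pair forms a hull
# edge iff every other point lies on one closed side of its line.
oracle_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
        on_hull[i] <- on_hull[j] <- TRUE
      }
    }
  }
  which(on_hull)
}

# Point-in-polygon by winding angle accumulation (independent of the
# crossing-number rasterizer).
oracle_in_poly <- function(px, py, vx, vy) {
  k <- length(vx)
  total <- 0
  for (e in seq_len(k)) {
    x1 <- vx[e] - px; y1 <- vy[e] - py
    x2 <- vx[if (e == k) 1 else e + 1] - px
    y2 <- vy[if (e == k) 1 else e + 1] - py
    total <- total + atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2)
  }
  abs(total) > pi
}

# Distance from a point to a polygon boundary, to exclude near-boundary
# cells from oracle comparisons where the boundary rule may differ.
dist_to_ring <- function(px, py, vx, vy) {
  k <- length(vx)
  dmin <- Inf
  for (e in seq_len(k)) {
    x1 <- vx[e]; y1 <- vy[e]
    x2 <- vx[if (e == k) 1 else e + 1]; y2 <- vy[if (e == k) 1 else e + 1]
    dx <- x2 - x1; dy <- y2 - y1
    t <- if (dx == 0 && dy == 0) 0 else
      max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / (dx^2 + dy^2)))
    dmin <- min(dmin, sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2))
  }
  dmin
}

# Closed-form haversine, written independently of the geosphere-backed one.
oracle_haversine <- function(lon1, lat1, lon2, lat2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(pmin(1, a)))
}
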
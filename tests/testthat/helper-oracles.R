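# Independent oracles, kept free of the package's own code paths.

# Closed-form point-to-segment distance: perpendicular formula
# |cross((b-a),(p-a))| / |b-a| when the projection parameter t lies in
# [0,1], else the nearer endpoint.
psd_closed_form <- function(p, a, b) {
  d <- b - a
  l2 <- sum(d^2)
  if (l2 == 0) return(list(dist = sqrt(sum((p - a)^2)), t = NA_real_))
  t <- sum((p - a) * d) / l2
  dist <- if (t < 0) sqrt(sum((p - a)^2))
  else if (t > 1) sqrt(sum((p - b)^2))
  else abs(d[1] * (p[2] - a[2]) - d[2] * (p[1] - a[1])) / sqrt(l2)
  list(dist = dist, t = t)
}

# Exhaustive minimum spanning tree length by enumerating all n^(n-2)
# labelled trees through their Pruefer sequences (vectorised decode).
brute_mst_length <- function(xy) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  if (n == 1L) return(0)
  if (n == 2L) return(D[1, 2])
  S <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  N <- nrow(S)
  deg <- matrix(1L, N, n)
  for (k in seq_len(n - 2L)) {
    idx <- cbind(seq_len(N), S[, k])
    deg[idx] <- deg[idx] + 1L
  }
  W_small <- matrix(rep(n:1, each = N), N, n)   # prefer smallest index
  W_large <- matrix(rep(1:n, each = N), N, n)
  total <- numeric(N)
  rows <- seq_len(N)
  for (k in seq_len(n - 2L)) {
    s <- S[, k]
    leaf <- max.col((deg == 1L) * W_small, ties.method = "first")
    total <- total + D[cbind(leaf, s)]
    deg[cbind(rows, leaf)] <- 0L
    idx <- cbind(rows, s)
    deg[idx] <- deg[idx] - 1L
  }
  v1 <- max.col((deg == 1L) * W_small, ties.method = "first")
  v2 <- max.col((deg == 1L) * W_large, ties.method = "first")
  min(total + D[cbind(v1, v2)])
}

# do two segments properly intersect or touch? (orientation test)
segments_cross <- function(s1, s2) {
  o <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  a <- s1[1:2]; b <- s1[3:4]; c <- s2[1:2]; d <- s2[3:4]
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2 && o3 != o4) || o1 == 0 || o2 == 0 || o3 == 0 || o4 == 0
}

# minimum distance between two segments by dense parametric sampling
dense_min_distance <- function(s1, s2, k = 1000L) {
  t <- seq(0, 1, length.out = k)
  a1 <- cbind(s1[1] + t * (s1[3] - s1[1]), s1[2] + t * (s1[4] - s1[2]))
  a2 <- cbind(s2[1] + t * (s2[3] - s2[1]), s2[2] + t * (s2[4] - s2[2]))
  dx <- outer(a1[, 1], a2[, 1], "-")
  dy <- outer(a1[, 2], a2[, 2], "-")
  sqrt(min(dx * dx + dy * dy))
}

rand_segment <- function(scale = 10) runif(4, -scale, scale)

default_params <- function() congruence_params(2, 2.5, 3, 4, 0.8)

# a quick 1-edge track fixture
track1 <- function(x1, y1, x2, y2, taxon = "t") {
  build_mst(rbind(c(x1, y1), c(x2, y2)), taxa = taxon)
}
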
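# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (C++ nearest neighbor, vectorized surface scan) so that
# agreement is a genuine cross-check.

oracle_dice <- function(a, b) {
  na <- sum(a$mask); nb <- sum(b$mask)
  2 * sum(a$mask & b$mask) / (na + nb)
}

oracle_volume <- function(s) sum(s$mask) * prod(s$grid$spacing)

oracle_centroid <- function(s) {
  idx <- which(s$mask, arr.ind = TRUE)
  ctr <- numeric(3)
  for (a in 1:3) ctr[a] <- s$grid$origin[a] + (mean(idx[, a]) - 1) * s$grid$spacing[a]
  ctr
}

# all-pairs directed nearest-neighbor distances, plain R
oracle_min_dists <- function(ref, target) {
  apply(ref, 1, function(p) {
    sqrt(min((target[, 1] - p[1])^2 + (target[, 2] - p[2])^2 +
               (target[, 3] - p[3])^2))
  })
}

# exposed-face count by direct 6-neighbor scan with explicit loops
oracle_exposed_faces <- function(mask) {
  d <- dim(mask)
  count <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      ni <- i + step[1]; nj <- j + step[2]; nk <- k + step[3]
      outside <- ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]
      if (outside || !mask[ni, nj, nk]) count <- count + 1L
    }
  }
  count
}

# textbook Pearson r and two-sided t-test p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# brute-force even-odd point-in-polygon (ray casting, scalar loop)
oracle_point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[j, 1] + (py - poly[j, 2]) * (poly[i, 1] - poly[j, 1]) /
        (poly[i, 2] - poly[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# majority vote across a list of logical masks
oracle_majority_vote <- function(masks) {
  votes <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), dim(m))))
  votes > length(masks) / 2
}
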
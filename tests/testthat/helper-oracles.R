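# Brute-force reference implementations used as independent oracles.
# Deliberately naive: explicit voxel-set enumeration and all-pairs distances,
# no shared code with the package internals.

oracle_dsc <- function(P, G) {
  p <- which(P != 0)
  g <- which(G != 0)
  2 * length(intersect(p, g)) / (length(p) + length(g))
}

oracle_directed_mean <- function(A, B) {
  # A, B: n x 3 coordinate matrices in mm
  mean(apply(A, 1, function(a) {
    sqrt(min(colSums((t(B) - a)^2)))
  }))
}

oracle_avd <- function(P, G, spacing = c(1, 1, 1)) {
  cp <- which(P != 0, arr.ind = TRUE) %*% diag(spacing)
  cg <- which(G != 0, arr.ind = TRUE) %*% diag(spacing)
  max(oracle_directed_mean(cp, cg), oracle_directed_mean(cg, cp))
}

oracle_surface <- function(R) {
  d <- dim(R)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (R[i, j, k] == 0) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    exposed <- apply(nb, 1, function(v) {
      any(v < 1) || any(v > d) || R[v[1], v[2], v[3]] == 0
    })
    out[i, j, k] <- any(exposed)
  }
  out
}

oracle_asd <- function(R, G, spacing = c(1, 1, 1)) {
  sR <- oracle_surface(R)
  sG <- oracle_surface(G)
  cr <- which(sR, arr.ind = TRUE) %*% diag(spacing)
  cg <- which(sG, arr.ind = TRUE) %*% diag(spacing)
  ds <- c(apply(cr, 1, function(a) sqrt(min(colSums((t(cg) - a)^2)))),
          apply(cg, 1, function(a) sqrt(min(colSums((t(cr) - a)^2)))))
  mean(ds)
}

# Distance from a point to a polyline (sequence of segments).
oracle_point_polyline_dist <- function(v, pts) {
  if (nrow(pts) == 1L) return(sqrt(sum((v - pts[1, ])^2)))
  dmin <- Inf
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    ab <- b - a
    t <- if (sum(ab^2) > 0) max(0, min(1, sum((v - a) * ab) / sum(ab^2))) else 0
    dmin <- min(dmin, sqrt(sum((v - a - t * ab)^2)))
  }
  dmin
}

random_mask <- function(dim = c(8L, 8L, 8L), p = 0.2) {
  array(stats::rbinom(prod(dim), 1, p), dim)
}

nonempty_mask <- function(dim = c(8L, 8L, 8L), p = 0.2) {
  repeat {
    m <- random_mask(dim, p)
    if (sum(m) > 0) return(m)
  }
}

# Tiny network configuration shared by fast unit tests.
tiny_net_config <- function(variant = "sequential_spatial_first") {
  networkConfig(encoderChannels = c(2L, 3L, 4L), nPool = 2L, variant = variant)
}
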
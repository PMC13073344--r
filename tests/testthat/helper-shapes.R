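# Digital test shapes (logical masks, pixel-center rendering) and
# independent brute-force geometry oracles.

disk_mask <- function(d, pad = 2) {
  r <- d / 2
  n <- ceiling(d) + 2 * pad + 1
  c0 <- (n + 1) / 2
  xx <- matrix(rep(1:n, each = n), n)
  yy <- matrix(rep(1:n, n), n)
  (xx - c0)^2 + (yy - c0)^2 <= r^2
}

square_mask <- function(s, pad = 2) {
  m <- matrix(FALSE, s + 2 * pad, s + 2 * pad)
  m[pad + seq_len(s), pad + seq_len(s)] <- TRUE
  m
}

rect_mask <- function(w, h, pad = 2) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# two equal disks of radius r along x, center distance 2 r (1 - overlap)
dumbbell_mask <- function(r, overlap = 0, pad = 3) {
  dist <- 2 * r * (1 - overlap)
  nx <- ceiling(dist + 2 * r) + 2 * pad + 1
  ny <- ceiling(2 * r) + 2 * pad + 1
  cy <- (ny + 1) / 2
  c1 <- pad + r + 1
  c2 <- c1 + dist
  xx <- matrix(rep(1:nx, each = ny), ny)
  yy <- matrix(rep(1:ny, nx), ny)
  ((xx - c1)^2 + (yy - cy)^2 <= r^2) | ((xx - c2)^2 + (yy - cy)^2 <= r^2)
}

# Brute-force convex hull of a point set (O(n^3) edge test): a directed pair
# (i, j) is a hull edge iff every other point lies on one side.  Vertices
# are ordered by angle around the centroid; perimeter and area are those of
# the raw polygon (no boundary correction).
brute_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  stopifnot(n >= 3)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- pts[j, ] - pts[i, ]
    cr <- v[1] * (pts[, 2] - pts[i, 2]) - v[2] * (pts[, 1] - pts[i, 1])
    if (all(cr >= -1e-9) || all(cr <= 1e-9)) on_hull[c(i, j)] <- TRUE
  }
  hp <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(hp)
  hp <- hp[order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1])), , drop = FALSE]
  q <- hp[c(2:nrow(hp), 1), , drop = FALSE]
  list(perimeter = sum(sqrt(rowSums((q - hp)^2))),
       area = abs(sum(hp[, 1] * q[, 2] - q[, 1] * hp[, 2])) / 2)
}

# match classified records to scene ground truth by nearest centroid;
# returns the truth classes aligned to the record rows
truth_classes <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i) {
    d2 <- (truth$center_x_um - records$centroid_x_um[i])^2 +
      (truth$center_y_um - records$centroid_y_um[i])^2
    truth$true_class[which.min(d2)]
  }, character(1))
}

# minimal particle-record rows for classification tests
make_record <- function(id = 1, convexity = 0.9, solidity = 0.95,
                        area_px = 200, intensity_sd = 20,
                        ce_diameter_um = 5, hs_circularity = 0.95) {
  data.frame(particle_id = id, convexity = convexity, solidity = solidity,
             area_px = area_px, intensity_sd = intensity_sd,
             ce_diameter_um = ce_diameter_um, hs_circularity = hs_circularity)
}
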
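# Shape-descriptor oracles: analytic limits of digital disks, squares,
# rectangles and disk dumbbells, plus invariance properties.

test_that("perimeter of digital disks converges to pi * d", {
  for (d in c(50, 100)) {
    p <- particle_perimeter(disk_mask(d))
    expect_lt(abs(p / (pi * d) - 1), 0.02)
  }
})

test_that("degenerate masks have the documented unit-cell perimeter", {
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(particle_perimeter(single), pi)
  expect_equal(particle_perimeter(single, pixel_size = 0.5), pi * 0.5)
  # 1 x 10 bar: center-line trace + unit-cell margin, close to the
  # 22-unit rectangle boundary (documented thin-structure bias < 1.5 px)
  bar <- rect_mask(10, 1)
  expect_lt(abs(particle_perimeter(bar) - 22), 1.5)
  expect_error(particle_perimeter(matrix(FALSE, 3, 3)), "empty")
})

test_that("large digital disks are near-perfect circles on all descriptors", {
  rec <- particle_descriptors(disk_mask(100))
  expect_gte(rec$hs_circularity, 0.98)
  expect_gte(rec$convexity, 0.98)
  expect_gte(rec$solidity, 0.98)
  expect_lte(rec$elongation, 0.05)
})

test_that("square circularity converges to pi / 4 from above", {
  circ <- vapply(c(50, 100, 200),
                 function(s) particle_descriptors(square_mask(s))$hs_circularity,
                 numeric(1))
  err <- circ - pi / 4
  expect_true(all(err > 0))         # perimeter underestimates 4s slightly
  expect_true(all(diff(err) < 0))   # and the bias shrinks with size
  expect_lt(err[3], 0.01)
  expect_equal(particle_descriptors(square_mask(100))$elongation, 0,
               tolerance = 0.02)
})

test_that("2:1 rectangle elongation is one half", {
  rec <- particle_descriptors(rect_mask(40, 20))
  expect_equal(rec$elongation, 0.5, tolerance = 0.02)
  expect_lte(rec$width_um, rec$length_um)
})

test_that("tangent disk dumbbell: solidity 2*pi/(4+pi), well below the individual thresholds", {
  # hull of two tangent equal circles = 2r x 2r rectangle (between the
  # centers) + two half-disks: area (4 + pi) r^2 against union area 2 pi r^2
  rec <- particle_descriptors(dumbbell_mask(40))
  expect_equal(rec$solidity, 2 * pi / (4 + pi), tolerance = 0.02)
  expect_lt(rec$hs_circularity, 0.920)
  expect_lt(rec$solidity, 0.970)
})

test_that("ce_diameter matches its closed form", {
  expect_equal(ce_diameter(pi * 25), 10)
  expect_equal(ce_diameter(pi / 4), 1)
  expect_equal(ce_diameter(100 * 0.0625^2), 0.705, tolerance = 5e-4)
  expect_error(ce_diameter(0), "positive")
  expect_error(ce_diameter(-3), "positive")
})

test_that("descriptors are scale-equivariant in pixel size", {
  m <- dumbbell_mask(25)
  a <- particle_descriptors(m, pixel_size = 1)
  b <- particle_descriptors(m, pixel_size = 2.5)
  for (f in c("ce_diameter_um", "perimeter_um", "length_um", "width_um"))
    expect_equal(b[[f]], 2.5 * a[[f]])
  expect_equal(b$area_um2, 2.5^2 * a$area_um2)
  for (f in c("hs_circularity", "convexity", "solidity", "elongation"))
    expect_equal(b[[f]], a[[f]])
})

test_that("descriptors are robust to 45-degree rotation", {
  # render an axis-aligned and a 45-degree rotated 60 x 30 rectangle by
  # pixel-center inclusion and compare descriptors
  rot_rect <- function(theta, w = 60, h = 30, n = 120) {
    xx <- matrix(rep(1:n, each = n), n) - (n + 1) / 2
    yy <- matrix(rep(1:n, n), n) - (n + 1) / 2
    u <- xx * cos(theta) + yy * sin(theta)
    v <- -xx * sin(theta) + yy * cos(theta)
    abs(u) <= w / 2 & abs(v) <= h / 2
  }
  a <- particle_descriptors(rot_rect(0))
  b <- particle_descriptors(rot_rect(pi / 4))
  expect_equal(b$area_um2, a$area_um2, tolerance = 0.02)
  expect_equal(b$perimeter_um, a$perimeter_um, tolerance = 0.02)
  expect_equal(b$elongation, a$elongation, tolerance = 0.02)
  expect_equal(b$solidity, a$solidity, tolerance = 0.02)
  # disks are the rotation-invariance limit
  d0 <- particle_descriptors(disk_mask(100))
  expect_equal(d0$hs_circularity, 1, tolerance = 0.02)
})

test_that("hull quantities agree with a brute-force hull on small shapes", {
  set.seed(11)
  for (rep in 1:6) {
    m <- matrix(stats::runif(144) < 0.45, 12, 12)
    lab <- label_particles(m, segmentation_config(min_pixels = 4,
                                                  border_policy = "keep"))
    if (lab$n_particles == 0) next
    cc <- which(lab$labels == 1L, arr.ind = TRUE)
    sub <- matrix(FALSE, 14, 14)
    sub[cbind(cc[, 1] + 1L, cc[, 2] + 1L)] <- TRUE
    tr <- trace_contour(sub)
    bp <- unique(tr$path)
    if (nrow(bp) < 3) next
    bh <- brute_hull(bp)
    rec <- particle_descriptors(sub)
    expect_equal(rec$hull_perimeter_um, bh$perimeter + pi, tolerance = 1e-8)
    expect_equal(rec$hull_area_um2, bh$area + bh$perimeter / 2 + pi / 4,
                 tolerance = 1e-8)
  }
})

test_that("intensity statistics are population moments on the 0-255 scale", {
  m <- matrix(FALSE, 4, 4); m[2, 2:3] <- TRUE; m[3, 2:3] <- TRUE
  img <- matrix(200, 4, 4)
  img[2, 2] <- 10; img[2, 3] <- 20; img[3, 2] <- 30; img[3, 3] <- 40
  rec <- particle_descriptors(m, img)
  expect_equal(rec$intensity_mean, 25)
  expect_equal(rec$intensity_sd, sqrt(mean((c(10, 20, 30, 40) - 25)^2)))
  flat <- particle_descriptors(m, matrix(77, 4, 4))
  expect_equal(flat$intensity_sd, 0)
})

test_that("shape mismatches and empty masks are rejected", {
  m <- disk_mask(10)
  expect_error(particle_descriptors(m, matrix(0, 2, 2)), "dimensions differ")
  expect_error(particle_descriptors(matrix(FALSE, 5, 5)), "empty")
})
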
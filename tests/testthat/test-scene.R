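# Synthetic scene generator: determinism, area fidelity, cluster geometry,
# ground-truth consistency, and the paired-measurement harness.

test_that("an empty scene is background plus noise with empty truth", {
  spec <- scene_spec(64, 48, n_individuals = 0, n_agglomerates = 0,
                     pixel_size_um = 0.2, noise_sd = 0, seed = 1)
  sc <- generate_scene(spec)
  expect_equal(dim(sc$image), c(48, 64))
  expect_true(all(sc$image == spec$background_level))
  expect_equal(nrow(sc$truth), 0L)
})

test_that("a single noise-free disk has analytic area and consistent truth", {
  # one 10 um disk at 0.5 um/px -> 20 px diameter
  spec <- scene_spec(64, 64, n_individuals = 1, n_agglomerates = 0,
                     pixel_size_um = 0.5, noise_sd = 0,
                     diameter_meanlog = log(10), diameter_sdlog = 0, seed = 2)
  sc <- generate_scene(spec)
  area_um2 <- sum(sc$image < spec$background_level) * 0.5^2
  expect_lt(abs(area_um2 / (pi * 25) - 1), 0.02)
  # true CE diameter equals the mask-area identity within one pixel-equivalent
  expect_equal(sc$truth$true_ce_diameter_um, ce_diameter(area_um2),
               tolerance = 0.5 / sc$truth$true_ce_diameter_um)
  expect_identical(sc$truth$true_class, "individual")
})

test_that("scene generation is deterministic in the seed", {
  spec <- scene_spec(256, 256, n_individuals = 10, n_agglomerates = 4,
                     pixel_size_um = 0.2, noise_sd = 6, seed = 9)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  spec2 <- scene_spec(256, 256, n_individuals = 10, n_agglomerates = 4,
                      pixel_size_um = 0.2, noise_sd = 6, seed = 10)
  expect_false(identical(generate_scene(spec2)$image, a$image))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  invisible(generate_scene(scene_spec(64, 64, 1, 0, pixel_size_um = 0.5,
                                      seed = 4)))
  expect_identical(stats::runif(1), before)
})

test_that("placed silhouettes never touch", {
  spec <- scene_spec(384, 384, n_individuals = 20, n_agglomerates = 6,
                     pixel_size_um = 0.2, noise_sd = 0, seed = 5)
  sc <- generate_scene(spec)
  lab <- label_particles(binarize(sc$image),
                         segmentation_config(min_pixels = 1,
                                             border_policy = "keep"))
  expect_equal(lab$n_particles, nrow(sc$truth))
})

test_that("overcrowded frames fail with an informative placement error", {
  spec <- scene_spec(96, 96, n_individuals = 200, n_agglomerates = 0,
                     pixel_size_um = 0.2, seed = 6)
  expect_error(generate_scene(spec, max_attempts = 50), "too crowded")
})

test_that("cluster silhouettes are single components with the right geometry", {
  expect_error(build_cluster(1, 5, 0.25), "outside")
  set.seed(8)
  m <- build_cluster(3, c(5, 4, 6), 0.25, pixel_size_um = 0.2)
  lab <- label_particles(m, segmentation_config(min_pixels = 1,
                                                border_policy = "keep"))
  expect_equal(lab$n_particles, 1L)  # 8-connected union
  # near-total overlap collapses to a single near-circular disk
  m1 <- build_cluster(2, c(6, 6), 0.95, pixel_size_um = 0.1,
                      directions = 0)
  rec <- particle_descriptors(m1)
  expect_gt(rec$hs_circularity, 0.95)
  # three near-tangent equal disks in a line: length ~ 6r, width ~ 2r
  m3 <- build_cluster(3, c(8, 8, 8), 0.02, pixel_size_um = 0.1,
                      directions = c(0, 0))
  rec3 <- particle_descriptors(m3)
  expect_gt(rec3$elongation, 0.5)
})

test_that("chain agglomerates at overlap <= 0.3 are morphologically separable", {
  set.seed(21)
  n <- 120
  circ <- vapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    m <- build_cluster(k, stats::rlnorm(k, log(4.5), 0.3), 0.3,
                       pixel_size_um = 0.2)
    mm <- matrix(FALSE, nrow(m) + 4, ncol(m) + 4)
    mm[3:(nrow(m) + 2), 3:(ncol(m) + 2)] <- m
    particle_descriptors(mm)$hs_circularity
  }, numeric(1))
  expect_gte(mean(circ < 0.920), 0.95)
})

test_that("paired simulations follow their linear model exactly when noiseless", {
  pm <- generate_paired(paired_sim_spec(20, slope = 1, intercept = 0,
                                        noise_sd = 0, seed = 3))
  expect_equal(pm$x, pm$y)
  pm2 <- generate_paired(paired_sim_spec(20, slope = 1, intercept = 1,
                                         noise_sd = 0, seed = 3))
  expect_equal(pm2$y - pm2$x, rep(1, 20))
  expect_identical(generate_paired(paired_sim_spec(10, seed = 5)),
                   generate_paired(paired_sim_spec(10, seed = 5)))
  expect_error(paired_sim_spec(2), "outside")
})

test_that("scenes round-trip through image and truth files", {
  spec <- scene_spec(128, 128, n_individuals = 4, n_agglomerates = 1,
                     pixel_size_um = 0.25, noise_sd = 5, seed = 12)
  sc <- generate_scene(spec)
  td <- withr::local_tempdir()
  png_path <- file.path(td, "scene.png")
  tif_path <- file.path(td, "scene.tif")
  csv_path <- file.path(td, "truth.csv")
  write_scene(sc, png_path, csv_path)
  write_grayscale_image(sc$image, tif_path)
  expect_equal(read_grayscale_image(png_path), unname(sc$image))
  expect_equal(read_grayscale_image(tif_path), unname(sc$image))
  tr <- utils::read.csv(csv_path)
  expect_equal(tr$true_ce_diameter_um, sc$truth$true_ce_diameter_um,
               tolerance = 1e-6)
})
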
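# Synthetic bright-field globule scenes with per-particle ground truth.
#
# Globules are near-circular fat droplets rendered as dark disks on a light
# background; agglomerates are chains of overlapping disks fused into one
# silhouette.  Every scene carries a ground-truth table so segmentation,
# morphometry and classification can be validated without any real data.

#' Specification of a synthetic globule scene
#'
#' Globule diameters follow a lognormal law (micrometres); each agglomerate
#' is a chain of `k` overlapping disks whose consecutive center spacing is
#' `(1 - overlap_fraction)` times the sum of their radii.  Disks are rendered
#' by pixel-center inclusion (hard mask) with a radial intensity ramp from
#' `particle_level` at the center to `rim_level` at the edge; keeping
#' `rim_level` below the segmentation threshold preserves the full silhouette
#' while giving particles a realistic internal contrast (intensity SD well
#' above the quality-control floor).
#'
#' @param width_px,height_px Frame size in pixels.
#' @param n_individuals Number of single-globule particles.
#' @param n_agglomerates Number of multi-globule agglomerates.
#' @param pixel_size_um Micrometres per pixel (default 0.0625: a 1.25 um
#'   camera pixel behind a 20x objective).
#' @param background_level,particle_level,rim_level Grayscale levels (0-255);
#'   `particle_level` must be darker than `background_level`.
#' @param noise_sd Additive Gaussian noise SD in grayscale units (>= 0).
#' @param diameter_meanlog,diameter_sdlog Lognormal parameters of the globule
#'   diameter law, on the log-micrometre scale (defaults `log(4.5)` and 0.3:
#'   median 4.5 um, the typical mature human-milk globule scale).
#' @param cluster_k_min,cluster_k_max Range of disks per agglomerate
#'   (uniform on `cluster_k_min:cluster_k_max`, both >= 2).
#' @param overlap_fraction Fractional overlap of consecutive cluster disks,
#'   in (0, 1) (default 0.25).
#' @param seed RNG seed (scene generation is deterministic given the spec).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px,
                       n_individuals, n_agglomerates,
                       pixel_size_um = 0.0625,
                       background_level = 230,
                       particle_level = 60,
                       rim_level = 140,
                       noise_sd = 0,
                       diameter_meanlog = log(4.5),
                       diameter_sdlog = 0.3,
                       cluster_k_min = 2,
                       cluster_k_max = 4,
                       overlap_fraction = 0.25,
                       seed = 1L) {
  check_scalar(width_px, "width_px", 8, integer = TRUE)
  check_scalar(height_px, "height_px", 8, integer = TRUE)
  check_scalar(n_individuals, "n_individuals", 0, integer = TRUE)
  check_scalar(n_agglomerates, "n_agglomerates", 0, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict_lo = TRUE)
  check_scalar(background_level, "background_level", 0, 255)
  check_scalar(particle_level, "particle_level", 0, 255)
  check_scalar(rim_level, "rim_level", 0, 255)
  if (particle_level >= background_level)
    stop("`particle_level` must be darker than `background_level`", call. = FALSE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(diameter_sdlog, "diameter_sdlog", 0)
  check_scalar(cluster_k_min, "cluster_k_min", 2, integer = TRUE)
  check_scalar(cluster_k_max, "cluster_k_max", cluster_k_min, integer = TRUE)
  check_scalar(overlap_fraction, "overlap_fraction", 0, 1,
               strict_lo = TRUE, strict_hi = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_individuals = as.integer(n_individuals),
                 n_agglomerates = as.integer(n_agglomerates),
                 pixel_size_um = pixel_size_um,
                 background_level = background_level,
                 particle_level = particle_level,
                 rim_level = rim_level,
                 noise_sd = noise_sd,
                 diameter_meanlog = diameter_meanlog,
                 diameter_sdlog = diameter_sdlog,
                 cluster_k_min = as.integer(cluster_k_min),
                 cluster_k_max = as.integer(cluster_k_max),
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Render the union of disks given centers (px, in a local frame) and radii
# (px).  Returns a list with the tight-bbox intensity stamp (NA outside the
# silhouette) and its logical mask.  Intensity ramps linearly with relative
# radial position; overlapping disks take the darker (minimum) value.
.render_disks <- function(cx, cy, r, particle_level, rim_level) {
  x0 <- floor(min(cx - r)); x1 <- ceiling(max(cx + r))
  y0 <- floor(min(cy - r)); y1 <- ceiling(max(cy + r))
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  xs <- matrix(rep(x0:x1, each = ny), ny)
  ys <- matrix(rep(y0:y1, nx), ny)
  val <- matrix(Inf, ny, nx)
  for (i in seq_along(cx)) {
    rho <- sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
    inside <- rho <= r[i]
    v <- particle_level + (rim_level - particle_level) * rho / r[i]
    val[inside] <- pmin(val[inside], v[inside])
  }
  mask <- is.finite(val)
  val[!mask] <- NA_real_
  list(value = val, mask = mask, x0 = x0, y0 = y0)
}

#' Build an agglomerate silhouette as a chain of overlapping disks
#'
#' Disks are placed sequentially: disk `i` sits at distance
#' `(1 - overlap_fraction) * (r[i-1] + r[i])` from disk `i-1` along a random
#' direction, producing a single fused 8-connected silhouette of the kind a
#' fat-globule agglomerate projects in bright field.
#'
#' @param k Number of disks (>= 2).
#' @param diameters_um Component diameters in micrometres (length `k`).
#' @param overlap_fraction Fractional overlap of consecutive disks, in (0, 1).
#' @param pixel_size_um Micrometres per pixel.
#' @param directions Optional vector of `k - 1` placement angles (radians);
#'   drawn uniformly when omitted (use [with_seed()]-style seeding upstream
#'   for determinism).
#' @return Logical silhouette mask (tight bounding box) with attributes
#'   `centers_px` (k x 2 matrix, local pixel coordinates) and `radii_px`.
#' @export
build_cluster <- function(k, diameters_um, overlap_fraction,
                          pixel_size_um = 0.0625, directions = NULL) {
  check_scalar(k, "k", 2, integer = TRUE)
  if (length(diameters_um) != k || any(diameters_um <= 0))
    stop("`diameters_um` must hold k positive diameters", call. = FALSE)
  check_scalar(overlap_fraction, "overlap_fraction", 0, 1,
               strict_lo = TRUE, strict_hi = TRUE)
  r <- diameters_um / (2 * pixel_size_um)
  if (is.null(directions)) directions <- stats::runif(k - 1, 0, 2 * pi)
  if (length(directions) != k - 1)
    stop("`directions` must have k - 1 angles", call. = FALSE)
  cx <- numeric(k); cy <- numeric(k)
  for (i in 2:k) {
    d <- (1 - overlap_fraction) * (r[i - 1] + r[i])
    cx[i] <- cx[i - 1] + d * cos(directions[i - 1])
    cy[i] <- cy[i - 1] + d * sin(directions[i - 1])
  }
  st <- .render_disks(cx, cy, r, 0, 1)
  structure(st$mask,
            centers_px = cbind(x = cx - st$x0 + 1, y = cy - st$y0 + 1),
            radii_px = r)
}

# dilate a logical mask by one pixel (8-connectivity), returned with a
# 1-pixel pad on every side
.dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h + 2L, w + 2L)
  for (dy in 0:2) for (dx in 0:2)
    out[dy + seq_len(h), dx + seq_len(w)] <-
      out[dy + seq_len(h), dx + seq_len(w)] | mask
  out
}

#' Generate a synthetic globule scene with ground truth
#'
#' Renders all particles of a [scene_spec()] at non-touching positions
#' (rejection sampling; any two silhouettes are separated by at least one
#' background pixel) and returns the 8-bit image together with a per-particle
#' ground-truth table.  Deterministic given the spec (including its seed).
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Placement attempts per particle before giving up
#'   (default 10000).
#' @return An object of class `mfg_scene`: list with `image` (0-255 matrix),
#'   `truth` (data frame: `particle_id`, `true_class`, `center_x_um`,
#'   `center_y_um`, `n_components`, `component_diameters_um`
#'   (semicolon-separated), `true_ce_diameter_um`), `pixel_size_um`, `spec`.
#' @export
generate_scene <- function(spec, max_attempts = 10000L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height_px; w <- spec$width_px
    img <- matrix(spec$background_level, h, w)
    occ <- matrix(FALSE, h, w)
    n_tot <- spec$n_individuals + spec$n_agglomerates
    truth <- vector("list", n_tot)
    draw_d <- function(n) stats::rlnorm(n, spec$diameter_meanlog, spec$diameter_sdlog)
    pid <- 0L
    classes <- rep(c("individual", "agglomerate"),
                   c(spec$n_individuals, spec$n_agglomerates))
    for (cls in classes) {
      pid <- pid + 1L
      if (cls == "individual") {
        comp_d <- draw_d(1)
        r <- comp_d / (2 * spec$pixel_size_um)
        st <- .render_disks(0, 0, r, spec$particle_level, spec$rim_level)
      } else {
        k <- sample(spec$cluster_k_min:spec$cluster_k_max, 1)
        comp_d <- draw_d(k)
        r <- comp_d / (2 * spec$pixel_size_um)
        dirs <- stats::runif(k - 1, 0, 2 * pi)
        cxk <- numeric(k); cyk <- numeric(k)
        for (i in 2:k) {
          d <- (1 - spec$overlap_fraction) * (r[i - 1] + r[i])
          cxk[i] <- cxk[i - 1] + d * cos(dirs[i - 1])
          cyk[i] <- cyk[i - 1] + d * sin(dirs[i - 1])
        }
        st <- .render_disks(cxk, cyk, r, spec$particle_level, spec$rim_level)
      }
      mh <- nrow(st$mask); mw <- ncol(st$mask)
      if (mh + 4L > h || mw + 4L > w)
        stop(sprintf(paste0("particle %d (bbox %d x %d px) cannot fit in the ",
                            "%d x %d frame at pixel size %g um"),
                     pid, mw, mh, w, h, spec$pixel_size_um), call. = FALSE)
      dil <- .dilate1(st$mask)  # (mh + 2) x (mw + 2)
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r0 <- sample.int(h - mh - 3L, 1) + 1L  # top row, keeping a 2 px margin
        c0 <- sample.int(w - mw - 3L, 1) + 1L
        sub <- occ[(r0 - 1L):(r0 + mh), (c0 - 1L):(c0 + mw)]
        if (!any(sub & dil)) {
          rows <- r0:(r0 + mh - 1L); cols <- c0:(c0 + mw - 1L)
          patch <- img[rows, cols]
          patch[st$mask] <- st$value[st$mask]
          img[rows, cols] <- patch
          occ[rows, cols] <- occ[rows, cols] | st$mask
          cc <- which(st$mask, arr.ind = TRUE)
          area_um2 <- nrow(cc) * spec$pixel_size_um^2
          truth[[pid]] <- data.frame(
            particle_id = pid,
            true_class = cls,
            center_x_um = (mean(cc[, 2]) + c0 - 1) * spec$pixel_size_um,
            center_y_um = (mean(cc[, 1]) + r0 - 1) * spec$pixel_size_um,
            n_components = length(comp_d),
            component_diameters_um = paste(signif(comp_d, 8), collapse = ";"),
            true_ce_diameter_um = ce_diameter(area_um2)
          )
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0("failed to place particle %d of %d after %d ",
                            "attempts: frame %d x %d px is too crowded ",
                            "(occupancy %.1f%%)"),
                     pid, n_tot, max_attempts, w, h, 100 * mean(occ)),
             call. = FALSE)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- clip(round(img), 0, 255)
    truth <- if (n_tot > 0) do.call(rbind, truth) else data.frame(
      particle_id = integer(0), true_class = character(0),
      center_x_um = numeric(0), center_y_um = numeric(0),
      n_components = integer(0), component_diameters_um = character(0),
      true_ce_diameter_um = numeric(0))
    structure(list(image = img, truth = truth,
                   pixel_size_um = spec$pixel_size_um, spec = spec),
              class = "mfg_scene")
  })
}

#' @export
print.mfg_scene <- function(x, ...) {
  cat(sprintf("<mfg_scene> %d x %d px (%.4g um/px), %d particle%s (%d individual, %d agglomerate)\n",
              ncol(x$image), nrow(x$image), x$pixel_size_um,
              nrow(x$truth), if (nrow(x$truth) == 1) "" else "s",
              sum(x$truth$true_class == "individual"),
              sum(x$truth$true_class == "agglomerate")))
  invisible(x)
}

#' Write a scene to disk (image + ground-truth sidecar)
#'
#' @param scene An `mfg_scene`.
#' @param image_path TIFF/PNG output path for the 8-bit image.
#' @param truth_path CSV output path for the ground-truth table.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_scene <- function(scene, image_path, truth_path) {
  stopifnot(inherits(scene, "mfg_scene"))
  write_grayscale_image(scene$image, image_path)
  utils::write.csv(scene$truth, truth_path, row.names = FALSE)
  invisible(c(image_path, truth_path))
}

#' Specification of a paired two-method simulation
#'
#' Method-A values are drawn from a lognormal law and method-B values follow
#' `y = intercept + slope * x + Normal(0, noise_sd)` — the harness used to
#' exercise the method-comparison statistics with known truth.
#'
#' @param n_samples Number of paired samples (>= 3).
#' @param slope,intercept True linear relation of method B to method A.
#' @param noise_sd Measurement-error SD of method B.
#' @param x_meanlog,x_sdlog Lognormal parameters of the method-A values.
#' @param seed RNG seed.
#' @return An object of class `paired_sim_spec`.
#' @export
paired_sim_spec <- function(n_samples, slope = 1, intercept = 0, noise_sd = 0,
                            x_meanlog = log(8), x_sdlog = 0.4, seed = 1L) {
  check_scalar(n_samples, "n_samples", 3, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_samples = as.integer(n_samples), slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 x_meanlog = x_meanlog, x_sdlog = x_sdlog,
                 seed = as.integer(seed)),
            class = "paired_sim_spec")
}

#' Generate paired two-method measurements
#'
#' @param spec A [paired_sim_spec()].
#' @return Data frame with columns `sample_id`, `x` (method A), `y`
#'   (method B); deterministic given the spec's seed.
#' @export
generate_paired <- function(spec) {
  stopifnot(inherits(spec, "paired_sim_spec"))
  with_seed(spec$seed, {
    x <- stats::rlnorm(spec$n_samples, spec$x_meanlog, spec$x_sdlog)
    y <- spec$intercept + spec$slope * x +
      stats::rnorm(spec$n_samples, 0, spec$noise_sd)
    data.frame(sample_id = seq_len(spec$n_samples), x = x, y = y)
  })
}
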
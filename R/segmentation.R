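# Threshold segmentation and connected-component labeling.
#
# The instrument's proprietary edge-detection is replaced by a documented
# scheme: the background is calibrated to `calibration_intensity * 255` and
# any pixel darker than `(1 - intensity_tolerance)` of that reference is
# foreground (dark particles on a light bright-field background).

#' Segmentation configuration
#'
#' Bundles the acquisition-SOP parameters controlling binarisation and
#' labeling: with the defaults (`calibration_intensity = 0.80`,
#' `intensity_tolerance = 0.20`) the foreground threshold is
#' `0.80 * 255 * 0.80 = 163.2` grayscale units.
#'
#' @param calibration_intensity Fraction of full grayscale taken as the
#'   calibrated background reference (default 0.80).
#' @param intensity_tolerance Fractional tolerance below the reference at
#'   which a pixel becomes foreground (default 0.20).
#' @param min_pixels Minimum component size in pixels (default 25).
#' @param max_particles Maximum admissible particle count (default 200000).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8, so diagonal
#'   bridges merge touching globules into one object).
#' @param border_policy `"exclude"` (default) drops components touching the
#'   frame border; `"keep"` retains them.
#' @param size_gate_um Two-element CE-diameter window in micrometres
#'   (default `c(1.5, 130)`); applied downstream at QC, not during labeling,
#'   so the gate is auditable.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(calibration_intensity = 0.80,
                                intensity_tolerance = 0.20,
                                min_pixels = 25,
                                max_particles = 200000,
                                connectivity = 8,
                                border_policy = c("exclude", "keep"),
                                size_gate_um = c(1.5, 130)) {
  check_scalar(calibration_intensity, "calibration_intensity", 0, 1, strict_lo = TRUE)
  check_scalar(intensity_tolerance, "intensity_tolerance", 0, 1,
               strict_lo = TRUE, strict_hi = TRUE)
  check_scalar(min_pixels, "min_pixels", 1, integer = TRUE)
  check_scalar(max_particles, "max_particles", 1, integer = TRUE)
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  border_policy <- match.arg(border_policy)
  if (length(size_gate_um) != 2L || size_gate_um[1] >= size_gate_um[2])
    stop("`size_gate_um` must be c(low, high) with low < high", call. = FALSE)
  structure(list(calibration_intensity = calibration_intensity,
                 intensity_tolerance = intensity_tolerance,
                 min_pixels = as.integer(min_pixels),
                 max_particles = as.integer(max_particles),
                 connectivity = as.integer(connectivity),
                 border_policy = border_policy,
                 size_gate_um = as.numeric(size_gate_um)),
            class = "segmentation_config")
}

#' Foreground threshold implied by a segmentation configuration
#' @param config A [segmentation_config()].
#' @return Threshold in grayscale units; pixels strictly below it are
#'   foreground.
#' @export
segmentation_threshold <- function(config) {
  config$calibration_intensity * 255 * (1 - config$intensity_tolerance)
}

#' Binarise a grayscale image
#'
#' A pixel is foreground iff its intensity is strictly below
#' `calibration_intensity * 255 * (1 - intensity_tolerance)`.
#'
#' @param image Single-channel numeric matrix with values in 0-255.
#' @param config A [segmentation_config()].
#' @return Logical matrix of foreground pixels.
#' @export
binarize <- function(image, config = segmentation_config()) {
  stop_if_not_image(image)
  image < segmentation_threshold(config)
}

#' Label connected foreground components
#'
#' Connected-component labeling under the configured connectivity (pixel
#' adjacency graph, components via igraph).  Components smaller than
#' `min_pixels` are dropped, components touching the frame border are dropped
#' under `border_policy = "exclude"`, and surviving components are relabeled
#' 1..n in raster-scan order of their first pixel.
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param config A [segmentation_config()].
#' @return An object of class `labeled_mask`: a list with `labels` (integer
#'   matrix, 0 = background), `n_particles`, and `config`.
#' @export
label_particles <- function(mask, config = segmentation_config()) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) > 0L) {
    vid <- integer(h * w)
    vid[fg] <- seq_along(fg)
    fgv <- as.vector(mask)
    rr <- ((fg - 1L) %% h) + 1L
    cc <- ((fg - 1L) %/% h) + 1L
    offs <- list(list(off = h, ok = cc < w),                    # right
                 list(off = 1L, ok = rr < h))                   # down
    if (config$connectivity == 8L) {
      offs <- c(offs,
                list(list(off = h + 1L, ok = cc < w & rr < h),  # down-right
                     list(off = h - 1L, ok = cc < w & rr > 1L)))# up-right
    }
    eds <- integer(0)
    for (o in offs) {
      a <- fg[o$ok]
      a <- a[fgv[a + o$off]]
      if (length(a)) eds <- c(eds, rbind(vid[a], vid[a + o$off]))
    }
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (length(eds)) g <- igraph::add_edges(g, eds)
    memb <- igraph::components(g)$membership
    labels[fg] <- memb

    sizes <- tabulate(memb)
    keep <- sizes >= config$min_pixels
    if (config$border_policy == "exclude") {
      border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
      border <- border[border > 0L]
      keep[border] <- FALSE
    }
    labels[fg][!keep[memb]] <- 0L
    kept_ids <- which(keep)
    if (length(kept_ids) > config$max_particles)
      stop(sprintf("particle count %d exceeds max_particles = %d",
                   length(kept_ids), config$max_particles), call. = FALSE)
    # relabel in raster order of first occurrence
    fg2 <- which(labels > 0L)
    if (length(fg2)) {
      old <- labels[fg2]
      first <- tapply(fg2, old, min)
      newid <- integer(max(old))
      newid[as.integer(names(first))] <- as.integer(rank(first))
      labels[fg2] <- newid[old]
    }
  }
  structure(list(labels = labels,
                 n_particles = as.integer(max(labels)),
                 config = config),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d particle%s\n",
              nrow(x$labels), ncol(x$labels), x$n_particles,
              if (x$n_particles == 1) "" else "s"))
  invisible(x)
}

#' Segment and measure an image in one call
#'
#' Convenience wrapper: binarise, label, and measure all particles.
#'
#' @param image Grayscale matrix (0-255).
#' @param pixel_size Micrometres per pixel.
#' @param config A [segmentation_config()].
#' @return Particle-record data frame (see [particle_descriptors()]).
#' @export
segment_image <- function(image, pixel_size = 1, config = segmentation_config()) {
  lab <- label_particles(binarize(image, config), config)
  measure_particles(lab, image, pixel_size)
}
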
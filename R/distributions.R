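# Number- and volume-weighted particle-size metrics on raw CE-diameter
# lists (no histogram binning: the imaging method records every particle's
# diameter individually).
#
# One percentile convention is used for both weightings: sort the diameters,
# form the cumulative weight fraction c_i (weights 1 for number, d^3 for
# volume, treating each particle as a sphere of its CE diameter), and
# interpolate the diameter linearly on the (c_i, d_i) pairs; targets at or
# below c_1 return the smallest diameter.  Because the cumulative volume
# fraction never exceeds the cumulative number fraction at any diameter, this
# shared rule guarantees Pv_p >= Pn_p at every percentile.

.weighted_percentile <- function(d, w, p) {
  ord <- order(d)
  ds <- d[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(p, function(pp) {
    f <- pp / 100
    if (f <= cw[1]) return(ds[1])
    stats::approx(cw, ds, xout = f, ties = "ordered", rule = 2)$y
  }, numeric(1))
}

.check_diameters <- function(diameters) {
  if (length(diameters) == 0L)
    stop("empty diameter list", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("all diameters must be positive and finite", call. = FALSE)
}

#' Number-weighted size metrics
#'
#' `D[1,0]` is the arithmetic mean diameter; `Pn10`, `Pn50`, `Pn90` are
#' number-percentile diameters under the package's cumulative-fraction
#' interpolation rule (see [volume_metrics()] for the shared convention).
#'
#' @param diameters Positive CE diameters in micrometres.
#' @return Named list: `d10`, `pn10`, `pn50`, `pn90`.
#' @examples
#' number_metrics(c(1, 2, 3))$d10  # 2
#' @export
number_metrics <- function(diameters) {
  .check_diameters(diameters)
  q <- .weighted_percentile(diameters, rep(1, length(diameters)), c(10, 50, 90))
  list(d10 = mean(diameters), pn10 = q[1], pn50 = q[2], pn90 = q[3])
}

#' Volume-weighted size metrics
#'
#' `D[4,3]` (De Brouckere mean) is `sum(d^4) / sum(d^3)`; `Pv10`, `Pv50`,
#' `Pv90` are the diameters at which the cumulative sphere-volume
#' (d^3-weighted) fraction of the sorted diameters crosses 10/50/90%,
#' linearly interpolated within the crossing step.  Treating agglomerates as
#' spheres of their CE diameter is a deliberate 2D-projection approximation.
#'
#' @param diameters Positive CE diameters in micrometres.
#' @return Named list: `d43`, `pv10`, `pv50`, `pv90`.
#' @examples
#' volume_metrics(c(1, 2))$d43  # 17/9
#' @export
volume_metrics <- function(diameters) {
  .check_diameters(diameters)
  q <- .weighted_percentile(diameters, diameters^3, c(10, 50, 90))
  list(d43 = sum(diameters^4) / sum(diameters^3),
       pv10 = q[1], pv50 = q[2], pv90 = q[3])
}

#' One-row size-distribution summary
#'
#' Combines [number_metrics()] and [volume_metrics()] with the particle
#' count.
#'
#' @param diameters Positive CE diameters in micrometres.
#' @return One-row data frame: `n`, `d10`, `pn10`, `pn50`, `pn90`, `d43`,
#'   `pv10`, `pv50`, `pv90`.
#' @export
size_summary <- function(diameters) {
  nm <- number_metrics(diameters)
  vm <- volume_metrics(diameters)
  data.frame(n = length(diameters),
             d10 = nm$d10, pn10 = nm$pn10, pn50 = nm$pn50, pn90 = nm$pn90,
             d43 = vm$d43, pv10 = vm$pv10, pv50 = vm$pv50, pv90 = vm$pv90)
}

#' Per-sample, per-class size summaries
#'
#' Applies [size_summary()] to the CE diameters of each (sample, class)
#' group of a classified particle table, including the `"total"` pseudo-class
#' covering all QC-passing particles.
#'
#' @param classified Data frame with `sample_id`, `class`, and
#'   `ce_diameter_um` columns.
#' @param sample_ids Sample ids expected in the output (defaults to those
#'   present); a sample with no particles yields a `"total"` row of missing
#'   values rather than disappearing.
#' @return Data frame with `sample_id`, `class`, and the [size_summary()]
#'   columns; within a sample, classes with no particles are omitted.
#' @export
summarize_samples <- function(classified,
                              sample_ids = unique(classified$sample_id)) {
  .require_cols(classified, c("sample_id", "class", "ce_diameter_um"))
  out <- list()
  for (sid in sample_ids) {
    sub <- classified[classified$sample_id == sid, ]
    if (nrow(sub) == 0L) {
      na_row <- size_summary(1)
      na_row[1, ] <- NA
      na_row$n <- 0L
      out[[length(out) + 1L]] <-
        cbind(data.frame(sample_id = as.character(sid), class = "total"),
              na_row)
      next
    }
    for (cls in c("total", "individual", "agglomerate")) {
      d <- if (cls == "total") sub$ce_diameter_um
           else sub$ce_diameter_um[sub$class == cls]
      if (length(d) == 0L) next
      out[[length(out) + 1L]] <-
        cbind(data.frame(sample_id = as.character(sid), class = cls),
              size_summary(d))
    }
  }
  if (length(out) == 0L)
    return(cbind(data.frame(sample_id = character(0), class = character(0)),
                 size_summary(1)[0, ]))
  do.call(rbind, out)
}
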
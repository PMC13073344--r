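# Quality-control filtering and individual/agglomerate classification.
#
# Particles failing any of four image-quality criteria (low convexity, low
# solidity, tiny pixel area, or flat internal intensity) are excluded as
# foreign matter or poor-quality detections; survivors are classified as
# individual globules (near-circular, below 25 um), agglomerates (low
# circularity AND low solidity), or left unclassified but still counted in
# the total.

#' Classification configuration
#'
#' Thresholds of the QC-exclusion filters and of the individual/agglomerate
#' rules.  All QC comparisons are strict (`<`), so a particle sitting exactly
#' at a threshold is kept; the circularity boundary is shared: `>= 0.920` is
#' individual-eligible, `< 0.920` agglomerate-eligible.
#'
#' @param min_convexity,min_solidity,min_area_px,min_intensity_sd QC floors
#'   (defaults 0.750, 0.700, 100 px, 10 grayscale units).
#' @param individual_min_circularity Individuals require HS circularity at or
#'   above this (default 0.920).
#' @param individual_max_ce_um Individuals require CE diameter strictly below
#'   this (default 25 um).
#' @param agglomerate_max_solidity Agglomerates require solidity strictly
#'   below this (default 0.970) in addition to circularity < 0.920.
#' @param size_gate_um CE-diameter window applied at QC (default
#'   `c(1.5, 130)`, inclusive).
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(min_convexity = 0.750,
                                  min_solidity = 0.700,
                                  min_area_px = 100,
                                  min_intensity_sd = 10,
                                  individual_min_circularity = 0.920,
                                  individual_max_ce_um = 25,
                                  agglomerate_max_solidity = 0.970,
                                  size_gate_um = c(1.5, 130)) {
  for (v in c(min_convexity, min_solidity, min_area_px, min_intensity_sd,
              individual_min_circularity, individual_max_ce_um,
              agglomerate_max_solidity, size_gate_um))
    if (!is.finite(v)) stop("all thresholds must be finite", call. = FALSE)
  if (length(size_gate_um) != 2L || size_gate_um[1] >= size_gate_um[2])
    stop("`size_gate_um` must be c(low, high) with low < high", call. = FALSE)
  structure(list(min_convexity = min_convexity,
                 min_solidity = min_solidity,
                 min_area_px = min_area_px,
                 min_intensity_sd = min_intensity_sd,
                 individual_min_circularity = individual_min_circularity,
                 individual_max_ce_um = individual_max_ce_um,
                 agglomerate_max_circularity = individual_min_circularity,
                 agglomerate_max_solidity = agglomerate_max_solidity,
                 size_gate_um = as.numeric(size_gate_um)),
            class = "classification_config")
}

.require_cols <- function(records, cols) {
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("records are missing required descriptor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Apply the quality-control exclusion filters
#'
#' A record is excluded iff `convexity < min_convexity` OR
#' `solidity < min_solidity` OR `area_px < min_area_px` OR
#' `intensity_sd < min_intensity_sd` (all strict), or its CE diameter falls
#' outside the size gate.  Excluded records carry every failed criterion in
#' an `exclusion_reason` column (comma-separated).
#'
#' @param records Particle-record data frame (see [particle_descriptors()]).
#' @param config A [classification_config()].
#' @param exclude_ids Optional particle ids to drop manually (reason
#'   `"manual"`), standing in for visual exclusion of bubbles or debris.
#' @return List with `kept` and `excluded` data frames; `excluded` has the
#'   extra `exclusion_reason` column.
#' @export
qc_filter <- function(records, config = classification_config(),
                      exclude_ids = NULL) {
  .require_cols(records, c("convexity", "solidity", "area_px",
                           "intensity_sd", "ce_diameter_um"))
  fail <- cbind(
    convexity = records$convexity < config$min_convexity,
    solidity = records$solidity < config$min_solidity,
    area = records$area_px < config$min_area_px,
    intensity_sd = records$intensity_sd < config$min_intensity_sd,
    size_gate = records$ce_diameter_um < config$size_gate_um[1] |
      records$ce_diameter_um > config$size_gate_um[2],
    manual = records$particle_id %in% exclude_ids
  )
  fail[is.na(fail)] <- FALSE
  bad <- rowSums(fail) > 0
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$exclusion_reason <- apply(fail[bad, , drop = FALSE], 1, function(f)
      paste(colnames(fail)[f], collapse = ","))
  } else {
    excluded$exclusion_reason <- character(0)
  }
  list(kept = records[!bad, , drop = FALSE], excluded = excluded)
}

#' Classify QC-passing particles as individual, agglomerate, or unclassified
#'
#' Individual: HS circularity >= 0.920 AND CE diameter < 25 um.
#' Agglomerate: HS circularity < 0.920 AND solidity < 0.970.
#' Everything else is `"unclassified"` but still counts towards the total.
#' The two rules partition on the shared circularity boundary, so every
#' record receives exactly one label.
#'
#' @param records QC-passing particle records.
#' @param config A [classification_config()].
#' @return `records` with an added `class` column.
#' @export
classify_particles <- function(records, config = classification_config()) {
  .require_cols(records, c("hs_circularity", "solidity", "ce_diameter_um"))
  circ <- records$hs_circularity
  cls <- rep("unclassified", nrow(records))
  cls[circ >= config$individual_min_circularity &
        records$ce_diameter_um < config$individual_max_ce_um] <- "individual"
  cls[circ < config$agglomerate_max_circularity &
        records$solidity < config$agglomerate_max_solidity] <- "agglomerate"
  records$class <- cls
  records
}

#' Per-sample class count table
#'
#' Counts and percentages of total/individual/agglomerate/unclassified
#' particles per sample, plus a mean (SD) summary row.  Percentages are
#' computed against the per-sample total; a zero-particle sample reports
#' `NA` percentages (undefined, not zero).
#'
#' @param classified Data frame of classified records with a `sample_id`
#'   column and a `class` column (from [classify_particles()]).
#' @param sample_ids Sample ids expected in the table (defaults to those
#'   present); a declared sample with no particles yields a zero-count row
#'   with `NA` percentages.
#' @return Data frame with columns `sample_id`, `n_total`, `n_individual`,
#'   `pct_individual`, `n_agglomerate`, `pct_agglomerate`, `n_unclassified`,
#'   `pct_unclassified`; the last two rows hold the across-sample mean and SD.
#' @export
tabulate_classes <- function(classified,
                             sample_ids = unique(classified$sample_id)) {
  .require_cols(classified, c("sample_id", "class"))
  ids <- sample_ids
  if (length(ids) == 0L)
    stop("no samples to tabulate", call. = FALSE)
  rows <- lapply(ids, function(sid) {
    cl <- classified$class[classified$sample_id == sid]
    n <- length(cl)
    ni <- sum(cl == "individual"); na_ <- sum(cl == "agglomerate")
    nu <- sum(cl == "unclassified")
    pct <- function(k) if (n == 0) NA_real_ else 100 * k / n
    data.frame(sample_id = as.character(sid), n_total = n,
               n_individual = ni, pct_individual = pct(ni),
               n_agglomerate = na_, pct_agglomerate = pct(na_),
               n_unclassified = nu, pct_unclassified = pct(nu))
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1, drop = FALSE]
  summ <- data.frame(sample_id = c("mean", "sd"),
                     rbind(colMeans(num, na.rm = TRUE),
                           apply(num, 2, stats::sd, na.rm = TRUE)))
  names(summ) <- names(tab)
  rbind(tab, summ)
}
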
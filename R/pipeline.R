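# End-to-end orchestration: image(s) -> particle records -> QC +
# classification -> per-class size summaries -> CSV bundle with a
# machine-readable run manifest; and the two-summary comparison report.

#' Analyze one or more micrograph images
#'
#' Runs the full pipeline (binarise, label, measure, QC-filter, classify,
#' summarise) on each image and, when `output_dir` is given, writes
#' `particles.csv` (all measured records), `classified.csv` (QC-passing
#' records with class labels and excluded records with reasons),
#' `summary.csv` (per-sample, per-class size metrics), and `manifest.json`
#' (configuration, inputs and package version, making the run reproducible).
#'
#' @param images Character vector of TIFF/PNG paths, or a (list of) numeric
#'   image matrices.
#' @param pixel_size Micrometres per pixel.
#' @param sample_ids Sample identifiers (defaults to file names or indices).
#' @param seg_config A [segmentation_config()].
#' @param class_config A [classification_config()].
#' @param output_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `particles`, `classified`, `excluded`,
#'   `counts`, `summary` data frames and `manifest`.
#' @export
analyze_images <- function(images, pixel_size,
                           sample_ids = NULL,
                           seg_config = segmentation_config(),
                           class_config = classification_config(),
                           output_dir = NULL) {
  if (is.matrix(images)) images <- list(images)
  from_files <- is.character(images)
  n <- length(images)
  if (is.null(sample_ids))
    sample_ids <- if (from_files) {
      sub("\\.[^.]+$", "", basename(images))
    } else as.character(seq_len(n))
  if (length(sample_ids) != n)
    stop("`sample_ids` must match the number of images", call. = FALSE)

  parts <- list(); classed <- list(); excl <- list()
  for (i in seq_len(n)) {
    img <- if (from_files) read_grayscale_image(images[[i]]) else images[[i]]
    rec <- segment_image(img, pixel_size, seg_config)
    if (nrow(rec)) rec$sample_id <- sample_ids[i] else rec$sample_id <- character(0)
    parts[[i]] <- rec
    qc <- qc_filter(rec, class_config)
    classed[[i]] <- classify_particles(qc$kept, class_config)
    excl[[i]] <- qc$excluded
  }
  particles <- do.call(rbind, parts)
  classified <- do.call(rbind, classed)
  excluded <- do.call(rbind, excl)
  counts <- if (nrow(classified)) tabulate_classes(classified) else NULL
  summary <- summarize_samples(classified, sample_ids = sample_ids)

  manifest <- list(
    package = "mfgmorph",
    version = as.character(utils::packageVersion("mfgmorph")),
    pixel_size_um = pixel_size,
    inputs = if (from_files) basename(images) else sprintf("matrix_%d", seq_len(n)),
    sample_ids = sample_ids,
    segmentation = unclass(seg_config),
    classification = unclass(class_config),
    n_particles = nrow(particles),
    n_excluded = nrow(excluded)
  )
  out <- list(particles = particles, classified = classified,
              excluded = excluded, counts = counts, summary = summary,
              manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(particles, file.path(output_dir, "particles.csv"),
                     row.names = FALSE)
    utils::write.csv(classified, file.path(output_dir, "classified.csv"),
                     row.names = FALSE)
    utils::write.csv(excluded, file.path(output_dir, "excluded.csv"),
                     row.names = FALSE)
    if (!is.null(counts))
      utils::write.csv(counts, file.path(output_dir, "counts.csv"),
                       row.names = FALSE)
    utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' Compare two methods' per-sample summaries
#'
#' Joins two summary tables (as produced by [analyze_images()] /
#' [summarize_samples()], or any table with `sample_id` and metric columns)
#' on sample id and runs [method_agreement()] for every shared metric,
#' producing one report row per metric (per class, when a `class` column is
#' present in both).
#'
#' @param a,b Data frames or CSV paths; `a` is method A (differences are
#'   A minus B).
#' @param metrics Metric columns to compare (default: the size metrics
#'   present in both tables).
#' @param labels Method names for the report.
#' @param n_resamples,seed Bootstrap control for the BCa intervals.
#' @param output_csv Optional path for the report.
#' @return Data frame with one row per (class, metric): n, r and BCa CI,
#'   paired-t p, CCC, mean bias, limits of agreement, proportional-bias
#'   slope and CI, and the proportional-bias flag.
#' @export
compare_methods <- function(a, b,
                            metrics = NULL,
                            labels = c("A", "B"),
                            n_resamples = 3000,
                            seed = NULL,
                            output_csv = NULL) {
  if (is.character(a)) a <- utils::read.csv(a)
  if (is.character(b)) b <- utils::read.csv(b)
  .require_cols(a, "sample_id"); .require_cols(b, "sample_id")
  if (is.null(metrics))
    metrics <- intersect(intersect(names(a), names(b)),
                         c("d10", "pn10", "pn50", "pn90",
                           "d43", "pv10", "pv50", "pv90"))
  if (length(metrics) == 0L) stop("no shared metric columns", call. = FALSE)
  by_class <- "class" %in% names(a) && "class" %in% names(b)
  classes <- if (by_class) intersect(unique(a$class), unique(b$class)) else NA

  rows <- list()
  for (cls in classes) {
    aa <- if (by_class) a[a$class == cls, ] else a
    bb <- if (by_class) b[b$class == cls, ] else b
    un <- setdiff(union(aa$sample_id, bb$sample_id),
                  intersect(aa$sample_id, bb$sample_id))
    if (length(un))
      stop("unmatched sample ids: ", paste(un, collapse = ", "), call. = FALSE)
    bb <- bb[match(aa$sample_id, bb$sample_id), ]
    for (mm in metrics) {
      fit <- method_agreement(aa[[mm]], bb[[mm]], labels = labels,
                              n_resamples = n_resamples, seed = seed)
      s <- summary(fit)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(class = if (by_class) cls else "all", metric = mm), s)
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(output_csv))
    utils::write.csv(report, output_csv, row.names = FALSE)
  report
}
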
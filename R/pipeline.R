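## End-to-end orchestration: ROI extraction, per-cell measurement, cohort
## profiling, density counting, and statistics behind one configuration.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end run. All physical
#' defaults mirror the published workflow: 10 counting fields of
#' 0.159 mm^2 per case, Sholl rings every 10 px, ROI upscaling 300 px ->
#' 1200 px, alpha 0.05.
#'
#' @param manifest path to the input manifest CSV (columns: `path`,
#'   `kind` (`"cell"` or `"field"`), `case_id`, `group`, `compartment`,
#'   optional `roi_center_row`, `roi_center_col`, optional
#'   `microns_per_px` per image).
#' @param out_dir output directory (created if missing).
#' @param microns_per_px default calibration for images without their own.
#' @param interval Sholl ring spacing, px.
#' @param mode intersection counting mode, `"pixel"` or `"run"`.
#' @param threshold `"otsu"` or a numeric threshold.
#' @param use_watershed split touching objects during cell segmentation.
#' @param max_gap gap-closing bridge limit, px (0 = off).
#' @param roi_side,roi_scale ROI crop side (px) and integer upscale factor
#'   applied when a manifest row carries an ROI center.
#' @param fields_per_case expected counting fields per case.
#' @param field_area counting field area, mm^2.
#' @param min_object_area minimum counted object area, um^2.
#' @param alpha FDR level for statistics.
#' @param seed integer seed for all randomness in the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir, microns_per_px = 0.25,
                            interval = 10, mode = c("pixel", "run"),
                            threshold = "otsu", use_watershed = FALSE,
                            max_gap = 0, roi_side = 300, roi_scale = 4,
                            fields_per_case = 10, field_area = 0.159,
                            min_object_area = 20, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(microns_per_px > 0, interval >= 1, max_gap >= 0, roi_side > 0,
            roi_scale >= 1, fields_per_case > 0, field_area > 0, alpha > 0,
            alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Extract and upscale a square region of interest
#'
#' Crops a `side x side` window centered on `center` and enlarges it by an
#' integer factor with nearest-neighbor interpolation (mask-safe). The
#' calibration is divided by the factor, so physical measurements are
#' unchanged. The published workflow extracts 300 x 300 px cells and
#' enlarges them 400% to 1200 x 1200 px.
#'
#' @param image a [calibrated_image()].
#' @param center (row, col) ROI center.
#' @param side ROI side, px (default 300).
#' @param scale_factor integer upscale factor `>= 1` (default 4).
#' @return a [calibrated_image()] of side `side * scale_factor`.
#' @export
extract_roi <- function(image, center, side = 300, scale_factor = 4) {
  stopifnot(inherits(image, "calibrated_image"), scale_factor >= 1,
            scale_factor == round(scale_factor))
  r0 <- round(center[1]) - floor(side / 2)
  c0 <- round(center[2]) - floor(side / 2)
  r1 <- r0 + side - 1; c1 <- c0 + side - 1
  if (r0 < 1 || c0 < 1 || r1 > nrow(image$pixels) || c1 > ncol(image$pixels))
    stop("ROI out of bounds: rows ", r0, "-", r1, ", cols ", c0, "-", c1)
  crop <- image$pixels[r0:r1, c0:c1]
  if (scale_factor > 1)
    crop <- crop[rep(seq_len(side), each = scale_factor),
                 rep(seq_len(side), each = scale_factor)]
  out <- calibrated_image(crop, image$microns_per_px / scale_factor,
                          case_id = image$case_id, group = image$group,
                          compartment = image$compartment)
  out$roi_scale <- scale_factor  # downstream raster regularization hint
  out
}

#' Run the full pipeline from a manifest
#'
#' Reads every image in the manifest; `cell` rows go through segmentation,
#' soma separation, optional gap closing, skeletonization, Sholl profiling
#' and the six metrics, then the cohort is median-stratified, assigned to
#' profiles, and compared across profiles; `field` rows are counted and
#' summed per case/compartment, and cumulative counts are compared across
#' groups within each compartment. Per-cell failures (e.g. zero primary
#' processes) are logged and excluded -- never silently dropped: the run
#' log reconciles rows in = rows out + exclusions. Identical config and
#' inputs produce byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `metrics`, `profiles`, `density`,
#'   `stats_metrics`, `stats_counts`, `exclusions`; files are written
#'   under `config$out_dir` (`metrics.csv`, `profiles.csv`,
#'   `density_counts.csv`, `stats_metrics.csv`, `stats_counts.csv`,
#'   `stats.json`, `run_log.txt`, `config.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- read.csv(config$manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "kind", "case_id", "group", "compartment") %in%
                  names(man)))
  log_lines <- c("astromorph pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("astromorph"))),
                 paste0("seed: ", config$seed),
                 paste0("coordinates: (row, col), 1-based, origin top-left"),
                 paste0("percentile_rule: linear interpolation (R type 7)"),
                 vapply(setdiff(names(config), c("manifest", "out_dir")),
                        function(k) paste0(k, ": ", config[[k]]), ""))
  exclusions <- data.frame(path = character(0), reason = character(0))
  metrics <- NULL
  density <- NULL

  with_seed(config$seed, {
    cells <- man[man$kind == "cell", , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      row <- cells[i, ]
      mpp <- if ("microns_per_px" %in% names(row) &&
                 is.finite(row$microns_per_px)) row$microns_per_px else
        config$microns_per_px
      res <- tryCatch({
        img <- read_image(row$path, microns_per_px = mpp,
                          case_id = row$case_id, group = row$group,
                          compartment = row$compartment)
        if (all(c("roi_center_row", "roi_center_col") %in% names(row)) &&
            is.finite(row$roi_center_row))
          img <- extract_roi(img, c(row$roi_center_row, row$roi_center_col),
                             side = config$roi_side,
                             scale_factor = config$roi_scale)
        measure_cell(img, threshold = config$threshold,
                     use_watershed = config$use_watershed,
                     max_gap = config$max_gap, interval = config$interval,
                     mode = config$mode,
                     cell_id = paste0(row$case_id, "_", i))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(path = row$path,
                                       reason = conditionMessage(res)))
        log_lines <- c(log_lines,
                       paste0("EXCLUDED cell ", row$path, ": ",
                              conditionMessage(res)))
      } else {
        attributes(res)[c("seg", "skeleton", "profile")] <- NULL
        metrics <- rbind(metrics, as.data.frame(res))
      }
    }

    fields <- man[man$kind == "field", , drop = FALSE]
    if (nrow(fields)) {
      key <- interaction(fields$case_id, fields$compartment, drop = TRUE)
      recs <- lapply(split(seq_len(nrow(fields)), key), function(idx) {
        counts <- vapply(idx, function(i) {
          row <- fields[i, ]
          mpp <- if ("microns_per_px" %in% names(row) &&
                     is.finite(row$microns_per_px)) row$microns_per_px else
            config$microns_per_px
          img <- read_image(row$path, microns_per_px = mpp)
          count_cells_in_field(img, min_object_area = config$min_object_area,
                               threshold = config$threshold)
        }, 0L)
        summarize_case(counts, case_id = fields$case_id[idx[1]],
                       group = fields$group[idx[1]],
                       compartment = fields$compartment[idx[1]])
      })
      density <- do.call(rbind, lapply(recs, function(r) {
        d <- as.data.frame(r)
        # pad to fields_per_case columns for a rectangular CSV
        want <- paste0("field_", seq_len(config$fields_per_case))
        for (w in setdiff(want, names(d))) d[[w]] <- NA_integer_
        d[, c("case_id", "group", "compartment", want, "cumulative")]
      }))
      rownames(density) <- NULL
      density <- density[order(density$compartment, density$group,
                               density$case_id), ]
    }
  })

  log_lines <- c(log_lines,
                 sprintf("cells_in: %d, cells_out: %d, exclusions: %d",
                         sum(man$kind == "cell"),
                         if (is.null(metrics)) 0L else nrow(metrics),
                         nrow(exclusions)))

  profiles <- NULL
  stats_metrics <- NULL
  if (!is.null(metrics) && nrow(metrics) > 0) {
    write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
              row.names = FALSE)
    profiles <- profile_cohort(metrics)
    write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
              row.names = FALSE)
    n_prof <- length(unique(profiles$profile_id[!is.na(profiles$profile_id)]))
    if (n_prof >= 2) {
      stats_metrics <- compare_profiles(profiles, alpha = config$alpha)
      write.csv(comparison_table(stats_metrics),
                file.path(config$out_dir, "stats_metrics.csv"),
                row.names = FALSE)
    }
  }

  stats_counts <- NULL
  if (!is.null(density) && nrow(density) > 0) {
    write.csv(density, file.path(config$out_dir, "density_counts.csv"),
              row.names = FALSE)
    stats_counts <- list()
    for (comp in sort(unique(density$compartment))) {
      d <- density[density$compartment == comp, ]
      samples <- split(d$cumulative, d$group)
      samples <- samples[lengths(samples) > 0]
      if (length(samples) >= 2)
        stats_counts[[comp]] <- targeted_posthoc(samples,
                                                 alpha = config$alpha,
                                                 metric = paste0("GFAP_count_",
                                                                 comp))
    }
    if (length(stats_counts))
      write.csv(comparison_table(stats_counts),
                file.path(config$out_dir, "stats_counts.csv"),
                row.names = FALSE)
  }

  report <- list(metrics = stats_report(stats_metrics),
                 counts = stats_report(stats_counts))
  jsonlite::write_json(report, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- config; cfg$mode <- as.character(cfg$mode)
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(metrics = metrics, profiles = profiles, density = density,
                 stats_metrics = stats_metrics, stats_counts = stats_counts,
                 exclusions = exclusions))
}

## flatten a list of group_comparison objects into one table
comparison_table <- function(stats_list) {
  if (is.null(stats_list) || !length(stats_list)) return(NULL)
  do.call(rbind, lapply(names(stats_list), function(m) {
    s <- stats_list[[m]]
    cbind(data.frame(metric = m, H = s$omnibus$H, p_omnibus = s$omnibus$p,
                     reference = s$reference, stringsAsFactors = FALSE),
          s$comparisons)
  }))
}

stats_report <- function(stats_list) {
  if (is.null(stats_list) || !length(stats_list)) return(NULL)
  lapply(stats_list, function(s)
    list(H = s$omnibus$H, df = s$omnibus$df, p = s$omnibus$p,
         method = s$omnibus$method, reference = s$reference,
         reference_tie = s$reference_tie, global_median = s$global_median,
         comparisons = s$comparisons))
}
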
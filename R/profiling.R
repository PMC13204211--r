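## Median stratification of a metric cohort and assignment of each cell to
## one of the six recurrent morphometric profiles.

#' Global medians and IQRs of a metric cohort
#'
#' Per-metric sample medians over the pooled cohort (compartments and
#' groups together, the published pooling), with 25th/75th percentiles
#' (linear-interpolation rule, R type 7).
#'
#' @param cohort data.frame with the six [metric_names()] columns.
#' @return an object of class `global_medians`: list with `medians` and
#'   `iqr` (2 x 6 matrix, rows q25/q75), plus `n`.
#' @export
global_medians <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0,
            all(metric_names() %in% names(cohort)))
  med <- vapply(metric_names(), function(m) median(cohort[[m]]), 0)
  iqr <- vapply(metric_names(), function(m)
    quantile(cohort[[m]], c(0.25, 0.75), names = FALSE, type = 7),
    numeric(2))
  rownames(iqr) <- c("q25", "q75")
  structure(list(medians = med, iqr = iqr, n = nrow(cohort)),
            class = "global_medians")
}

#' @export
print.global_medians <- function(x, ...) {
  cat(sprintf("<global_medians> n = %d cells\n", x$n))
  for (m in metric_names())
    cat(sprintf("  %-24s %8.3g (IQR %.3g-%.3g)\n", m, x$medians[m],
                x$iqr["q25", m], x$iqr["q75", m]))
  invisible(x)
}

#' Binarize a metric vector against global medians
#'
#' Each metric becomes `"above"` when its value strictly exceeds the
#' global median and `"below"` otherwise; ties go below (small cohorts
#' frequently have data points equal to the median, so the tie rule is
#' explicit).
#'
#' @param vector a `metric_vector`, one-row data.frame, or named numeric
#'   vector with the six metrics.
#' @param medians a [global_medians()] object or named numeric vector.
#' @return named character vector of `"above"`/`"below"` in
#'   [metric_names()] order.
#' @export
binarize_metrics <- function(vector, medians) {
  med <- if (inherits(medians, "global_medians")) medians$medians else medians
  vals <- extract_metric_values(vector)
  setNames(ifelse(vals > med[metric_names()], "above", "below"),
           metric_names())
}

extract_metric_values <- function(vector) {
  if (is.data.frame(vector)) {
    stopifnot(nrow(vector) == 1)
    vapply(metric_names(), function(m) as.numeric(vector[[m]]), 0)
  } else {
    stopifnot(all(metric_names() %in% names(vector)))
    vector[metric_names()]
  }
}

#' Assign a cell to one of the six morphometric profiles
#'
#' Looks the above/below pattern up in the profile signature table
#' ([profile_signatures()]). Profiles 4 and 6 share a pattern
#' (process-dominant, below-median soma) and are separated by a
#' documented, swappable rule: within the cohort, a cell whose
#' total-intersection percentile rank exceeds its max-process-length
#' percentile rank is the densely branching type (profile 4), otherwise
#' the long-reach type (profile 6). Patterns matching no signature are
#' reported as `"unclassified"`, never forced to a nearest profile.
#'
#' @param pattern six `"above"`/`"below"` symbols from
#'   [binarize_metrics()].
#' @param vector the cell's metric values (needed only for the 4/6 rule).
#' @param cohort the full metric cohort data.frame (rank context for the
#'   4/6 rule).
#' @return an object of class `profile_assignment`: list with `pattern`,
#'   `profile_id` (integer 1-6 or `NA` for unclassified), and
#'   `disambiguator_used` flag.
#' @export
assign_profile <- function(pattern, vector = NULL, cohort = NULL) {
  stopifnot(length(pattern) == 6, all(pattern %in% c("above", "below")))
  # unnamed patterns are taken in metric_names() order
  if (!is.null(names(pattern))) pattern <- pattern[metric_names()]
  sig <- profile_signatures()  # columns already in metric_names() order
  hits <- which(apply(sig, 1, function(row) all(row == pattern)))
  disamb <- FALSE
  if (length(hits) == 0) {
    id <- NA_integer_
  } else if (length(hits) == 1) {
    id <- as.integer(hits)
  } else {
    # shared 4/6 pattern
    stopifnot(identical(as.integer(hits), c(4L, 6L)))
    if (is.null(vector) || is.null(cohort))
      stop("cohort context required to separate profiles 4 and 6")
    vals <- extract_metric_values(vector)
    rk <- function(metric) {
      x <- cohort[[metric]]
      (sum(x < vals[metric]) + 0.5 * sum(x == vals[metric])) / length(x)
    }
    id <- if (rk("total_intersections") > rk("max_process_length")) 4L else 6L
    disamb <- TRUE
  }
  structure(list(pattern = setNames(pattern, metric_names()),
                 profile_id = id, disambiguator_used = disamb),
            class = "profile_assignment")
}

#' @export
print.profile_assignment <- function(x, ...) {
  lab <- if (is.na(x$profile_id)) "unclassified" else
    paste0("profile ", x$profile_id)
  cat(sprintf("<profile_assignment> %s%s [%s]\n", lab,
              if (x$disambiguator_used) " (4/6 disambiguator)" else "",
              paste(substr(x$pattern, 1, 1), collapse = "")))
  invisible(x)
}

#' Stratify and assign a whole cohort
#'
#' Computes pooled global medians, binarizes every cell, and assigns each
#' to a profile. Assignment depends only on the cell's values and the
#' cohort (permuting cohort rows leaves results unchanged).
#'
#' @param cohort data.frame with the six metric columns (plus any
#'   metadata columns, carried through).
#' @param medians optional precomputed [global_medians()]; computed from
#'   the cohort when missing.
#' @return the cohort with added columns `pattern_<metric>` (6 columns),
#'   `profile_id` (integer, `NA` = unclassified), and
#'   `disambiguator_used`; the `global_medians` object is attached as an
#'   attribute.
#' @export
profile_cohort <- function(cohort, medians = NULL) {
  if (is.null(medians)) medians <- global_medians(cohort)
  n <- nrow(cohort)
  pats <- matrix(NA_character_, n, 6,
                 dimnames = list(NULL, paste0("pattern_", metric_names())))
  ids <- integer(n)
  dis <- logical(n)
  for (i in seq_len(n)) {
    pat <- binarize_metrics(cohort[i, ], medians)
    asg <- assign_profile(pat, cohort[i, ], cohort)
    pats[i, ] <- pat
    ids[i] <- ifelse(is.na(asg$profile_id), NA_integer_, asg$profile_id)
    dis[i] <- asg$disambiguator_used
  }
  out <- cbind(cohort, as.data.frame(pats), profile_id = ids,
               disambiguator_used = dis)
  attr(out, "global_medians") <- medians
  out
}
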
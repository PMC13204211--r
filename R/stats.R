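## Nonparametric statistical scheme: median/IQR summaries, tie-corrected
## Kruskal-Wallis (exact permutation null for small samples), the
## Benjamini-Krieger-Yekutieli two-stage FDR procedure, and the targeted
## reference-profile post hoc design.

#' Median and interquartile range of a sample
#'
#' The percentile rule is pinned to linear interpolation (R quantile
#' type 7) and recorded in reports, since software defaults differ.
#'
#' @param sample nonempty numeric vector.
#' @return list with `median`, `q25`, `q75`, `n`.
#' @examples
#' describe(1:9)$median  # 5
#' @export
describe <- function(sample) {
  if (!length(sample)) stop("empty sample")
  q <- quantile(sample, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(sample))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Mid-ranks over the pooled data; the H statistic is divided by the
#' standard tie-correction factor. The p-value comes from the chi-square
#' distribution with `k - 1` degrees of freedom, except when the pooled
#' sample size is at most `exact_n_max`, where the exact permutation null
#' (all distinct assignments of the pooled values to groups of the
#' observed sizes) is enumerated instead. With all observations tied, H is
#' defined as 0 and p as 1.
#'
#' @param samples list (optionally named) of `>= 2` nonempty numeric
#'   vectors.
#' @param exact_n_max largest pooled n for which the exact permutation
#'   p-value is used (default 10).
#' @return list with `H`, `p`, `df`, `method` (`"chi-square"` or
#'   `"permutation"`), and `n` per group.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$H  # 7.2
#' @export
kruskal_wallis <- function(samples, exact_n_max = 10L) {
  stopifnot(is.list(samples), length(samples) >= 2)
  ns <- lengths(samples)
  if (any(ns == 0)) stop("every group must contain at least one observation")
  x <- unlist(samples, use.names = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations in total")
  g <- rep(seq_along(samples), ns)
  H <- kw_statistic(x, g, ns)
  df <- length(samples) - 1L
  if (n <= exact_n_max) {
    p <- kw_exact_p(x, ns, H)
    method <- "permutation"
  } else {
    p <- pchisq(H, df = df, lower.tail = FALSE)
    method <- "chi-square"
  }
  if (is.na(H)) { H <- 0; p <- 1 }  # all observations tied
  list(H = H, p = p, df = df, method = method, n = ns)
}

## tie-corrected H; NA when every observation is tied
kw_statistic <- function(x, g, ns) {
  n <- length(x)
  r <- rank(x)
  Rj <- vapply(split(r, g), sum, 0)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) return(NA_real_)
  H / C
}

## exact permutation p-value: enumerate all distinct splits of the pooled
## indices into groups of sizes ns (feasible for n <= ~10)
kw_exact_p <- function(x, ns, H_obs) {
  if (is.na(H_obs)) return(1)
  n <- length(x)
  splits <- enumerate_splits(seq_len(n), ns)
  r <- rank(x)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  Hs <- vapply(splits, function(idx) {
    Rj <- vapply(idx, function(i) sum(r[i]), 0)
    h <- 12 / (n * (n + 1)) * sum(Rj^2 / ns) - 3 * (n + 1)
    h / C
  }, 0)
  mean(Hs >= H_obs - 1e-10)
}

## all assignments of `ids` into ordered groups of sizes ns (first group
## chosen by combn, recursively)
enumerate_splits <- function(ids, ns) {
  if (length(ns) == 1) return(list(list(ids)))
  first <- combn(ids, ns[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_splits(setdiff(ids, f), ns[-1])
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

#' Benjamini-Krieger-Yekutieli two-stage FDR procedure
#'
#' Stage 1 runs a linear step-up at level `alpha' = alpha / (1 + alpha)`
#' and uses its rejection count `r1` to estimate the number of true nulls
#' `m0 = m - r1`; stage 2 reruns the step-up at level `alpha' * m / m0`.
#' Reported `q` values satisfy `reject <=> q <= alpha`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return list with `reject` (logical, input order), `q` (adjusted
#'   values), `m0` (estimated true nulls), `alpha`.
#' @export
bky_fdr <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), alpha > 0, alpha < 1)
  m <- length(pvals)
  if (m == 0)
    return(list(reject = logical(0), q = numeric(0), m0 = 0L, alpha = alpha))
  ap <- alpha / (1 + alpha)
  r1 <- step_up_count(pvals, ap)
  if (r1 == m) {
    reject <- rep(TRUE, m)
    m0 <- 1L
  } else {
    m0 <- m - r1
    reject <- step_up_reject(pvals, ap * m / m0)
  }
  # q consistent with the decisions: q_(i) = (1+alpha) * m0 * min_{j>=i} p_(j)/j
  o <- order(pvals)
  ps <- pvals[o]
  q_sorted <- pmin(1, (1 + alpha) * m0 * rev(cummin(rev(ps / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(reject = reject, q = q, m0 = as.integer(m0), alpha = alpha)
}

## number of rejections of the BH linear step-up at level a
step_up_count <- function(pvals, a) {
  m <- length(pvals)
  ps <- sort(pvals)
  k <- which(ps <= seq_len(m) * a / m)
  if (length(k)) max(k) else 0L
}

step_up_reject <- function(pvals, a) {
  m <- length(pvals)
  k <- step_up_count(pvals, a)
  if (k == 0) return(rep(FALSE, m))
  thr <- sort(pvals)[k]
  pvals <= thr
}

#' Targeted post hoc comparisons against the most central profile
#'
#' For one morphometric parameter, the reference is the profile whose
#' median is closest to the global median of the pooled data (ties go to
#' the lower profile id, flagged). Every other profile is compared to the
#' reference with a two-sample rank-sum test (normal approximation with
#' tie and continuity correction; the pairwise statistic is a documented,
#' swappable choice), and the raw p-values pass through [bky_fdr()].
#'
#' @param samples named list mapping profile id to a numeric sample;
#'   `>= 2` entries.
#' @param alpha FDR level (default 0.05).
#' @param metric optional parameter name recorded in the output.
#' @return an object of class `group_comparison`: list with `metric`,
#'   `omnibus` (the [kruskal_wallis()] result), `reference`,
#'   `reference_tie` flag, `global_median`, `comparisons` (data.frame:
#'   `profile`, `n`, `median`, `q25`, `q75`, `p_raw`, `q`, `reject`), and
#'   `alpha`.
#' @export
targeted_posthoc <- function(samples, alpha = 0.05, metric = NA_character_) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples))) names(samples) <- seq_along(samples)
  pooled <- unlist(samples, use.names = FALSE)
  gmed <- median(pooled)
  meds <- vapply(samples, median, 0)
  dev <- abs(meds - gmed)
  ref_candidates <- which(dev == min(dev))
  reference <- names(samples)[min(ref_candidates)]
  reference_tie <- length(ref_candidates) > 1
  others <- setdiff(names(samples), reference)
  p_raw <- vapply(others, function(p) {
    pv <- suppressWarnings(
      wilcox.test(samples[[p]], samples[[reference]], exact = FALSE,
                  correct = TRUE)$p.value)
    if (!is.finite(pv)) 1 else pv
  }, 0)
  fdr <- bky_fdr(p_raw, alpha)
  desc <- lapply(others, function(p) describe(samples[[p]]))
  comparisons <- data.frame(
    profile = others,
    n = vapply(desc, function(d) d$n, 0L),
    median = vapply(desc, function(d) d$median, 0),
    q25 = vapply(desc, function(d) d$q25, 0),
    q75 = vapply(desc, function(d) d$q75, 0),
    p_raw = p_raw, q = fdr$q, reject = fdr$reject,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(metric = metric,
                 omnibus = kruskal_wallis(samples),
                 reference = reference, reference_tie = reference_tie,
                 global_median = gmed, comparisons = comparisons,
                 alpha = alpha,
                 percentile_rule = "linear interpolation (R type 7)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s KW H = %.3f, df = %d, p = %.4g (%s)\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$omnibus$H, x$omnibus$df, x$omnibus$p, x$omnibus$method))
  cat(sprintf("  reference: %s (median %.4g, global %.4g)%s\n", x$reference,
              median(x$comparisons$median), x$global_median,
              if (x$reference_tie) " [tie, lower id chosen]" else ""))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Profile-wise statistics for every metric of a profiled cohort
#'
#' Runs the omnibus Kruskal-Wallis test and the targeted BKY-corrected
#' post hoc design for each of the six metrics, grouping cells by their
#' assigned profile (unclassified cells are dropped, with a message).
#'
#' @param profiled cohort data.frame with a `profile_id` column (from
#'   [profile_cohort()]) or a `true_profile` column.
#' @param alpha FDR level.
#' @return named list of `group_comparison`, one per metric (metrics whose
#'   grouping has fewer than 2 profiles are skipped).
#' @export
compare_profiles <- function(profiled, alpha = 0.05) {
  idcol <- if ("profile_id" %in% names(profiled)) "profile_id" else
    "true_profile"
  keep <- !is.na(profiled[[idcol]])
  if (any(!keep))
    message(sum(!keep), " unclassified cell(s) excluded from statistics")
  dat <- profiled[keep, ]
  out <- list()
  for (m in metric_names()) {
    samples <- split(dat[[m]], dat[[idcol]])
    samples <- samples[lengths(samples) > 0]
    if (length(samples) < 2) next
    out[[m]] <- targeted_posthoc(samples, alpha = alpha, metric = m)
  }
  out
}
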
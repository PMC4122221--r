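#' Relative difference measure (RDM*) of two topographies
#'
#' Shape-difference statistic between two potential maps sampled at the same
#' points: the Euclidean distance between the two unit-normalized vectors,
#' \deqn{RDM^* = \sqrt{\sum_j \left(\frac{V_j^{RM}}{\|V^{RM}\|} -
#'   \frac{V_j^{TM}}{\|V^{TM}\|}\right)^2}.}
#' Zero means identical spatial profiles, 2 opposite profiles; the statistic
#' is symmetric and invariant to positive rescaling of either argument.
#'
#' @param v_rm,v_tm Equal-length potential vectors (reference and test model);
#'   both must have nonzero Euclidean norm.
#' @return RDM* in [0, 2].
#' @export
rdm_star <- function(v_rm, v_tm) {
  if (length(v_rm) != length(v_tm)) stop("vectors must have equal length")
  if (length(v_rm) < 1L) stop("vectors must be non-empty")
  na <- sqrt(sum(v_rm^2))
  nb <- sqrt(sum(v_tm^2))
  if (na == 0 || nb == 0) stop("zero-norm input: normalization undefined")
  sqrt(sum((v_rm / na - v_tm / nb)^2))
}

#' Magnification factor (MAG) of a test topography
#'
#' Ratio of root-sum-square magnitudes, test model over reference model:
#' \deqn{MAG = \sqrt{\sum_k (V_k^{TM})^2} \big/ \sqrt{\sum_k (V_k^{RM})^2}.}
#' Unity means equal magnitude; values above 1 mean the test topography is
#' stronger than the reference.
#'
#' @inheritParams rdm_star
#' @return MAG (> 0 for nonzero test input).
#' @export
mag <- function(v_rm, v_tm) {
  if (length(v_rm) != length(v_tm)) stop("vectors must have equal length")
  nr <- sqrt(sum(v_rm^2))
  if (nr == 0) stop("zero-norm reference: MAG undefined")
  sqrt(sum(v_tm^2)) / nr
}

#' Percent reduction of a peak potential by an added layer
#'
#' `100 * (1 - peak_with_layer / peak_ref_removed)`: how much (in percent) the
#' layer reduces the peak relative to the layer-removed model.
#'
#' @param peak_ref_removed Peak potential of the layer-removed model (V).
#' @param peak_with_layer Potential at the same location in the layered model.
#' @return Percent reduction.
#' @export
percent_peak_reduction <- function(peak_ref_removed, peak_with_layer) {
  if (peak_ref_removed == 0) stop("zero reference peak")
  100 * (1 - peak_with_layer / peak_ref_removed)
}

#' Histogram / CDF summary of a potential sample
#'
#' Equal-width histogram over `[min, max]`, empirical CDF at the sorted
#' values, mean, and population standard deviation (entire surfaces are
#' enumerated, so the population form is appropriate).
#'
#' @param values Numeric sample (n >= 1).
#' @param n_bins Number of histogram bins (default 50).
#' @return A `distribution_summary`: list with `breaks`, `counts`, `mids`,
#'   `cdf_x` (sorted values), `cdf_f` (cumulative fractions), `mean`, `sd`,
#'   `n`.
#' @export
distribution_summary <- function(values, n_bins = 50L) {
  stopifnot(length(values) >= 1L, n_bins >= 1L)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    breaks <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_bins + 1L)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  xs <- sort(values)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 cdf_x = xs, cdf_f = seq_along(xs) / length(xs),
                 mean = mean(values),
                 sd = sqrt(mean((values - mean(values))^2)),
                 n = length(values)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("Distribution summary: n = ", x$n,
      ", mean = ", signif(x$mean, 4),
      ", population sd = ", signif(x$sd, 4), "\n", sep = "")
  invisible(x)
}

#' Empirical CDF fraction at a threshold
#'
#' @param summary A `distribution_summary`.
#' @param q Threshold(s).
#' @return Fraction of the sample `<= q`.
#' @export
cdf_at <- function(summary, q) {
  vapply(q, function(t) mean(summary$cdf_x <= t), 0)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic `D = sup_x |F_x(t) - F_y(t)|` is evaluated exactly at the
#' pooled order statistics (ties handled by evaluating both ECDFs at every
#' pooled value); the p-value comes from the asymptotic two-sample Kolmogorov
#' distribution with effective size `n_x n_y / (n_x + n_y)` (via
#' [stats::ks.test()]).
#'
#' @param x,y Non-empty numeric samples.
#' @param alpha Decision level for the `different` flag (default 0.05).
#' @return List with `statistic`, `p_value`, `different` (p < alpha), `n_x`,
#'   `n_y`.
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) mean(x <= t), 0)
  fy <- vapply(pooled, function(t) mean(y <= t), 0)
  D <- max(abs(fx - fy))
  p <- suppressWarnings(
    stats::ks.test(x, y, exact = FALSE)$p.value)
  list(statistic = D, p_value = p, different = p < alpha,
       n_x = length(x), n_y = length(y))
}

#' Compare two potential topographies
#'
#' Bundles the comparison statistics for two maps sampled at the same points:
#' RDM*, MAG (test over reference), the two-sample K-S test on their value
#' distributions, and per-input mean / population sd.
#'
#' @param v_rm,v_tm Reference and test potential vectors (equal length).
#' @param n_bins Histogram bins for the distribution summaries.
#' @return A `comparison_result`: list with `rdm_star`, `mag`,
#'   `ks_statistic`, `ks_p`, `n_points`, `mean_rm`, `sd_rm`, `mean_tm`,
#'   `sd_tm`, `summary_rm`, `summary_tm`.
#' @export
compare_topographies <- function(v_rm, v_tm, n_bins = 50L) {
  ks <- ks_two_sample(v_rm, v_tm)
  sr <- distribution_summary(v_rm, n_bins)
  st <- distribution_summary(v_tm, n_bins)
  structure(list(rdm_star = rdm_star(v_rm, v_tm), mag = mag(v_rm, v_tm),
                 ks_statistic = ks$statistic, ks_p = ks$p_value,
                 ks_different = ks$different, n_points = length(v_rm),
                 mean_rm = sr$mean, sd_rm = sr$sd,
                 mean_tm = st$mean, sd_tm = st$sd,
                 summary_rm = sr, summary_tm = st),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Topography comparison (", x$n_points, " points)\n",
      "  RDM* = ", signif(x$rdm_star, 4),
      "   MAG = ", signif(x$mag, 4), "\n",
      "  K-S D = ", signif(x$ks_statistic, 4),
      ", p = ", format.pval(x$ks_p, digits = 3),
      if (x$ks_different) "  (distributions differ at alpha = 0.05)" else "",
      "\n  sd(reference) = ", signif(x$sd_rm, 4),
      " V, sd(test) = ", signif(x$sd_tm, 4), " V\n", sep = "")
  invisible(x)
}
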
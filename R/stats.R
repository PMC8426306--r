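## Longitudinal biomarker statistics: progression scores, fold changes,
## predictive correlations and non-parametric group comparisons.

#' CT progression score (delta-CT)
#'
#' Change in mean lung density between two imaging days,
#' `MLD(end) - MLD(start)`; positive values indicate progression.
#' Imaging days within `day_tolerance` of the nominal day are accepted
#' (FDG and FMISO sessions sit on consecutive days).
#'
#' @param timeline Data frame for one animal with columns `day` and
#'   `mld_hu` (one row per CT).
#' @param start_day,end_day Nominal days (defaults 9 and 23).
#' @param day_tolerance Accepted |day - nominal| slack.
#' @param animal_id Used in error messages.
#' @return A `progression_score` list: `delta_ct_hu`, `start_day`,
#'   `end_day`.
#' @export
delta_ct <- function(timeline, start_day = 9, end_day = 23, day_tolerance = 1,
                     animal_id = "animal") {
  pick <- function(nominal) {
    d <- abs(timeline$day - nominal)
    ok <- which(d <= day_tolerance & is.finite(timeline$mld_hu))
    if (!length(ok))
      stop("no CT for ", animal_id, " at day ", nominal)
    timeline$mld_hu[ok[which.min(d[ok])]]
  }
  structure(list(delta_ct_hu = pick(end_day) - pick(start_day),
                 start_day = start_day, end_day = end_day),
            class = "progression_score")
}

#' Fold change between group means
#'
#' Ratio of group means, `mean(a) / mean(b)`. Mean lung density must be
#' compared on the `"hu1000"` scale (HU + 1000, a physical-density
#' proxy), since raw HU values are negative in the lung.
#'
#' @param a,b Numeric vectors (e.g. per-animal metric values of two
#'   groups).
#' @param scale `"linear"` or `"hu1000"`.
#' @export
group_fold_change <- function(a, b, scale = c("linear", "hu1000")) {
  scale <- match.arg(scale)
  if (!length(a) || !length(b)) stop("empty group in fold change")
  if (scale == "hu1000") { a <- a + 1000; b <- b + 1000 }
  mb <- mean(b)
  if (mb == 0) stop("zero denominator in fold change")
  mean(a) / mb
}

#' Predictive correlation between an early marker and an outcome
#'
#' Pearson product-moment correlation (Spearman available) with a
#' two-sided p-value; pairs with missing values are dropped.
#'
#' @param early,outcome Paired numeric vectors per animal.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @export
predictive_correlation <- function(early, outcome,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(early) & is.finite(outcome)
  x <- early[ok]; y <- outcome[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate correlation: zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

## Exact two-sided Mann-Whitney p by exhaustive enumeration of all
## group assignments of the pooled sample (handles ties; the U statistic
## counts ties as 1/2).
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  dev_obs <- abs(u_of(seq_len(n1)) - n1 * (n - n1) / 2)
  idx_all <- combn(n, n1)
  devs <- apply(idx_all, 2, function(ix) abs(u_of(ix) - n1 * (n - n1) / 2))
  mean(devs >= dev_obs - 1e-9)
}

#' Non-parametric group comparison
#'
#' Two groups: two-sided Mann-Whitney (Wilcoxon rank-sum), exact by
#' exhaustive enumeration for small samples (ties included). More than
#' two groups: Kruskal-Wallis rank ANOVA.
#'
#' @param samples List of numeric vectors, one per group (all n >= 1).
#' @param exact_max Largest number of assignments enumerated exactly;
#'   beyond it the two-group test falls back on [stats::wilcox.test()].
#' @return List with `p`, `method`, `stars`.
#' @export
compare_groups <- function(samples, exact_max = 50000) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(lengths(samples) == 0)) stop("group with no observations")
  if (length(samples) == 2) {
    x <- samples[[1]]; y <- samples[[2]]
    n_assign <- choose(length(x) + length(y), length(x))
    if (n_assign <= exact_max) {
      p <- mw_enumerate(x, y)
      method <- "Mann-Whitney (exact)"
    } else {
      p <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      method <- "Mann-Whitney (normal approximation)"
    }
  } else {
    g <- factor(rep(seq_along(samples), lengths(samples)))
    p <- suppressWarnings(kruskal.test(unlist(samples), g)$p.value)
    if (is.nan(p)) p <- 1  # all observations identical: no evidence
    method <- "Kruskal-Wallis"
  }
  list(p = p, method = method, stars = significance_stars(p))
}

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#' @param p P-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
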
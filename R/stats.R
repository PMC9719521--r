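#' Cohort assessment statistics
#'
#' The statistics used to assess nucleosome profile features across a
#' cohort: linear-fit correlation of a feature against tumor fraction
#' with the RMSE of that fit, Benjamini-Hochberg FDR adjustment, the
#' paired Wilcoxon signed-rank test for before/after comparisons, mean
#' absolute deviation for no-tumor cohorts, and ANCOVA for differential
#' accessibility with tumor fraction as a covariate.
#'
#' @name cohort-stats
NULL

#' Feature vs tumor fraction correlation and linear fit
#'
#' Ordinary least squares of feature on tumor fraction; Pearson r with a
#' two-sided p-value via the t transform; RMSE is the root mean squared
#' residual of the fitted line (denominator n).
#'
#' @param feature numeric feature values (e.g. central coverage).
#' @param tumor_fraction numeric, same length.
#' @return A one-row data.frame of class `CorrelationResult`: `r`, `p`,
#'   `slope`, `intercept`, `rmse`, `n`.
#' @export
correlate_vs_tumor_fraction <- function(feature, tumor_fraction) {
  ok <- !is.na(feature) & !is.na(tumor_fraction)
  x <- tumor_fraction[ok]; y <- feature[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("tumor fraction is constant")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  rmse <- sqrt(mean(res^2))
  syy <- sum((y - mean(y))^2)
  r <- if (syy == 0) 0 else slope * sqrt(sxx / syy)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  out <- data.frame(r = r, p = p, slope = slope, intercept = intercept,
                    rmse = rmse, n = n)
  class(out) <- c("CorrelationResult", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `p_adj_(i) = min over j >= i of p_(j) * m / j`,
#' capped at 1, returned in the input order. `NA`s propagate and do not
#' count toward `m`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- ok[order(p[ok])]
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out[ord] <- pmin(adj, 1)
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on `after - before`. Zero differences are dropped.
#' With no ties in the absolute differences and `n <= exact_max`, the
#' exact null distribution of the signed-rank statistic is used;
#' otherwise the normal approximation with continuity and tie
#' correction. The reported statistic is the smaller of the positive
#' and negative rank sums.
#'
#' @param before,after paired numeric vectors.
#' @param exact_max largest n for the exact null (default 25).
#' @return List with `statistic`, `p`, `n` (nonzero pairs), `method`.
#' @export
paired_wilcoxon <- function(before, after, exact_max = 25) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) stop("no nonzero differences")
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0]); w_neg <- sum(rk[d < 0])
  w_min <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    p <- min(1, 2 * stats::psignrank(w_min, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_min - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approximation"
  }
  list(statistic = w_min, p = p, n = n, method = method)
}

#' Mean absolute deviation
#'
#' Mean of `|x - center(x)|`. Default centering is the mean; the median
#' is available via `center`.
#'
#' @param values numeric vector.
#' @param center `"mean"` (default) or `"median"`.
#' @return Non-negative scalar.
#' @export
mad_mean <- function(values, center = c("mean", "median")) {
  center <- match.arg(center)
  values <- values[!is.na(values)]
  c0 <- if (center == "mean") mean(values) else stats::median(values)
  mean(abs(values - c0))
}

#' ANCOVA for differential accessibility
#'
#' Ordinary least squares of `feature ~ group + covariate`; the group
#' effect is tested with a Type II F-test (full model vs covariate-only
#' model). No interaction term. A constant covariate degrades gracefully
#' to one-way ANOVA.
#'
#' @param feature numeric dependent variable.
#' @param group factor-like independent variable (two or more levels).
#' @param covariate numeric covariate (e.g. tumor fraction).
#' @return A one-row data.frame of class `AncovaResult`: `F`, `p` for
#'   the group term; `covariate_coef`, `covariate_p`.
#' @export
ancova <- function(feature, group, covariate) {
  df <- data.frame(y = feature, g = factor(group), x = covariate)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$g)) < 2) stop("need at least two groups")
  const_cov <- stats::sd(df$x) == 0
  full <- if (const_cov) stats::lm(y ~ g, df) else stats::lm(y ~ g + x, df)
  reduced <- if (const_cov) stats::lm(y ~ 1, df) else stats::lm(y ~ x, df)
  cmp <- stats::anova(reduced, full)
  fval <- cmp$F[2]; pval <- cmp$`Pr(>F)`[2]
  if (const_cov) {
    cc <- NA_real_; cp <- NA_real_
  } else {
    sm <- summary(full)$coefficients
    cc <- sm["x", "Estimate"]; cp <- sm["x", "Pr(>|t|)"]
  }
  out <- data.frame(F = fval, p = pval, covariate_coef = cc,
                    covariate_p = cp)
  class(out) <- c("AncovaResult", "data.frame")
  out
}

#' Compare feature tables before and after correction
#'
#' For each site list, fits feature vs tumor fraction before and after
#' correction, reports both RMSEs and MADs, and summarizes the paired
#' RMSE change with a Wilcoxon signed-rank test across site lists.
#'
#' @param before,after numeric matrices samples x site lists of a
#'   feature (e.g. central coverage), identically shaped and named.
#' @param tumor_fraction per-sample tumor fraction.
#' @return List with `table` (one row per site list: `site_list`,
#'   `rmse_before`, `rmse_after`, `mad_before`, `mad_after`,
#'   `r_before`, `r_after`), `wilcoxon` (test on the RMSE pairs, or
#'   `NULL` with a warning when degenerate), and `fraction_reduced`.
#' @export
compare_correction_modes <- function(before, after, tumor_fraction) {
  stopifnot(identical(dim(before), dim(after)))
  lists <- colnames(before)
  if (is.null(lists)) lists <- paste0("list", seq_len(ncol(before)))
  tab <- do.call(rbind, lapply(seq_along(lists), function(j) {
    cb <- correlate_vs_tumor_fraction(before[, j], tumor_fraction)
    ca <- correlate_vs_tumor_fraction(after[, j], tumor_fraction)
    data.frame(site_list = lists[j],
               rmse_before = cb$rmse, rmse_after = ca$rmse,
               mad_before = mad_mean(before[, j]),
               mad_after = mad_mean(after[, j]),
               r_before = cb$r, r_after = ca$r)
  }))
  wt <- tryCatch(paired_wilcoxon(tab$rmse_before, tab$rmse_after),
                 error = function(e) {
                   warning("degenerate RMSE comparison: ", conditionMessage(e))
                   NULL
                 })
  list(table = tab, wilcoxon = wt,
       fraction_reduced = mean(tab$rmse_after < tab$rmse_before))
}
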
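# Comparison statistics: mean-mean concordance r^2, Welch-test differential
# expression, Storey-Tibshirani q-values, ROC-like curves, union/intersection
# combination of gene lists, over/under-detection areas, and the variance and
# ranking tests used to compare methods.

#' Mean-mean concordance for one treatment group
#'
#' Computes per-gene group means on each platform and the squared Pearson
#' correlation between them (the concordance statistic `r^2`). For technical
#' replicates of a common RNA pool the points should fall on `y = x`.
#'
#' @param d A `combined_dataset`.
#' @param group Treatment label, present on both platforms.
#' @param ccc Also report the concordance correlation coefficient.
#' @return List with `r2`, the `points` data frame (gene, mean1, mean2) and,
#'   if requested, `ccc`.
#' @export
mean_mean_r2 <- function(d, group, ccc = FALSE) {
  ann <- d$annotation
  s1 <- intersect(colnames(d$platform1), ann$sample_id[ann$treatment == group])
  s2 <- intersect(colnames(d$platform2), ann$sample_id[ann$treatment == group])
  if (length(s1) == 0L || length(s2) == 0L)
    stop_validation("concordance undefined: treatment '", group,
                    "' is missing from one platform")
  m1 <- rowMeans(unclass(d$platform1)[, s1, drop = FALSE])
  m2 <- rowMeans(unclass(d$platform2)[, s2, drop = FALSE])
  out <- list(r2 = stats::cor(m1, m2)^2,
              points = data.frame(gene = dataset_genes(d), mean1 = m1, mean2 = m2,
                                  row.names = NULL))
  if (ccc) {
    # Lin's concordance correlation coefficient
    out$ccc <- 2 * stats::cov(m1, m2) /
      (stats::var(m1) + stats::var(m2) + (mean(m1) - mean(m2))^2)
  }
  out
}

#' Per-gene two-sided Welch t-test p-values
#'
#' Vectorized over genes: unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom. Genes with zero variance in both
#' groups get `p = 1` when the means are equal and `p = 0` otherwise.
#'
#' @param m Genes x samples matrix (e.g. [merged_matrix()] output).
#' @param group_a,group_b Sample id (or column index) vectors, >= 2 each.
#' @return Named numeric vector of p-values, one per gene.
#' @export
welch_pvalues <- function(m, group_a, group_b) {
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop_validation("each group needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
    message(sum(degenerate), " zero-variance gene(s) assigned degenerate p-values")
  }
  names(p) <- rownames(m)
  p
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion `pi0` from `pi0(lambda) = #\{p > lambda\} /
#' (G (1 - lambda))` on `lambda = 0, 0.05, ..., 0.95`, smoothed by a cubic
#' smoothing spline (3 effective df) and evaluated at the largest lambda,
#' clamped to (0, 1]. Q-values follow the step-down rule
#' `q(p_(G)) = pi0 p_(G)`, `q(p_(i)) = min(pi0 G p_(i) / i, q(p_(i+1)))`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda_grid Grid for the `pi0` estimate.
#' @return List with `qvalues` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, lambda_grid = seq(0, 0.95, by = 0.05)) {
  if (length(p) == 0L) stop_validation("empty p-value list")
  if (any(p < 0 | p > 1)) stop_validation("p-values must lie in [0, 1]")
  G <- length(p)
  if (G < 20L) {
    warning("fewer than 20 p-values; pi0 forced to 1 (spline unstable)")
    pi0 <- 1
  } else {
    pi0_lambda <- vapply(lambda_grid, function(l) sum(p > l) / (G * (1 - l)),
                         numeric(1L))
    fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(G)
  q[G] <- pi0 * ps[G]
  if (G > 1L) for (i in (G - 1L):1L) q[i] <- min(pi0 * G * ps[i] / i, q[i + 1L])
  out <- numeric(G)
  out[ord] <- q
  names(out) <- names(p)
  list(qvalues = out, pi0 = pi0)
}

#' FDR grid shared by all ROC-like curves (step 0.001 on [0, 1])
#' @noRd
fdr_grid <- function() seq(0, 1, by = 0.001)

#' ROC-like curve of a q-value list
#'
#' The empirical cdf of the q-values on an FDR grid with step 0.001: the
#' fraction of genes called differentially expressed as a function of the
#' FDR threshold.
#'
#' @param q Vector of q-values.
#' @return List with `grid` and non-decreasing `height` in `[0, 1]`.
#' @export
roc_like_curve <- function(q) {
  grid <- fdr_grid()
  list(grid = grid, height = stats::ecdf(q)(grid))
}

#' Combine two q-value lists by gene-set union or intersection
#'
#' Union takes the gene-wise minimum of the two lists, intersection the
#' gene-wise maximum, mirroring union/intersection of detected gene sets at
#' every FDR threshold.
#'
#' @param q1,q2 Q-value vectors over the same gene list (matching names when
#'   named).
#' @param mode `"union"` or `"intersection"`.
#' @return Combined q-value vector.
#' @export
combine_qlists <- function(q1, q2, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(q1) != length(q2) ||
      (!is.null(names(q1)) && !is.null(names(q2)) && !identical(names(q1), names(q2))))
    stop_validation("mismatched gene lists")
  if (mode == "union") pmin(q1, q2) else pmax(q1, q2)
}

#' Over- and under-detection areas
#'
#' `o` (over-detection) is the trapezoid area between the ROC-like curve of
#' the cross-platform q-list and the curve of its gene-wise intersection with
#' the union of the two native (single-platform) lists: genes detected with
#' merged data but with neither platform alone. `u` (under-detection) is the
#' area between the curve of the native intersection and that of its
#' intersection with the cross-platform list: genes detected by both
#' platforms independently but lost after normalization.
#'
#' @param q_cross Q-values from the cross-platform normalized data.
#' @param q_native1,q_native2 Q-values from each platform alone, same genes.
#' @return List with areas `o` and `u` (both in `[0, 1]`).
#' @export
detection_areas <- function(q_cross, q_native1, q_native2) {
  if (length(q_cross) != length(q_native1) || length(q_cross) != length(q_native2))
    stop_validation("mismatched gene lists")
  q_union <- pmin(q_native1, q_native2)
  q_inter <- pmax(q_native1, q_native2)
  grid <- fdr_grid()
  h <- function(q) stats::ecdf(q)(grid)
  o <- pracma::trapz(grid, h(q_cross) - h(pmax(q_cross, q_union)))
  u <- pracma::trapz(grid, h(q_inter) - h(pmax(q_inter, q_cross)))
  list(o = o, u = u)
}

#' Brown-Forsythe test for equality of variances
#'
#' Levene-type test on the absolute deviations from the group medians,
#' delegated to [car::leveneTest()] with `center = median`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `statistic` (F) and `p.value`.
#' @export
brown_forsythe <- function(groups) {
  if (length(groups) < 2L) stop_validation("need >= 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop_validation("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  res <- car::leveneTest(y, g, center = stats::median)
  list(statistic = res[1L, "F value"], p.value = res[1L, "Pr(>F)"])
}

#' Rank method performance distributions with significance marks
#'
#' Orders methods by the median of their statistic distributions and tests
#' each adjacent pair with a two-sided Mann-Whitney U-test at level
#' `alpha_base / n^2` (`n` = number of methods including controls). Adjacent
#' pairs that differ significantly are marked `"<"`, others `","`.
#'
#' @param distributions Named list: method -> numeric vector of statistic
#'   values.
#' @param alpha_base Base significance level (default 0.05).
#' @param decreasing Order from best (largest median) to worst; set `FALSE`
#'   for statistics where smaller is better.
#' @return List with `order` (method names), `medians`, `marks` (length
#'   n - 1) and the formatted `ranking` string.
#' @export
rank_methods <- function(distributions, alpha_base = 0.05, decreasing = FALSE) {
  if (length(distributions) < 2L) stop_validation("need >= 2 methods")
  if (any(vapply(distributions, length, integer(1L)) < 2L))
    stop_validation("each method needs >= 2 values")
  n <- length(distributions)
  meds <- vapply(distributions, stats::median, numeric(1L), na.rm = TRUE)
  ord <- order(meds, decreasing = decreasing)
  alpha <- alpha_base / n^2
  marks <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- distributions[[ord[i]]]; b <- distributions[[ord[i + 1L]]]
    pv <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    marks[i] <- if (!is.na(pv) && pv < alpha) "<" else ","
  }
  nm <- names(distributions)[ord]
  ranking <- paste0(nm[1L],
                    paste0(vapply(seq_len(n - 1L), function(i)
                      paste0(" ", marks[i], " ", nm[i + 1L]), character(1L)),
                      collapse = ""))
  list(order = nm, medians = meds[ord], marks = marks, ranking = ranking,
       alpha = alpha)
}
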
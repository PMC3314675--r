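# Distribution- and rank-based cross-platform normalization methods:
# quantile normalization (QN), median rank scores (MRS), gene quantiles (GQ),
# quantile discretization (QD), normal discretization (NorDi), and the
# distribution transformation (DisTran).

#' Quantile normalization across both platforms
#'
#' Pools all samples from both platforms and maps every sample onto the
#' per-rank mean of the pooled samples, so all samples share one marginal
#' distribution afterwards. Ties receive the mean of their tied reference
#' values. Delegates the rank transform to [limma::normalizeQuantiles()].
#'
#' @param d A `combined_dataset` with continuous values.
#' @return The normalized `combined_dataset`.
#' @export
quantile_normalize <- function(d) {
  check_continuous(d)
  merged <- merged_matrix(d)
  if (any(apply(merged, 2L, function(x) diff(range(x)) == 0)))
    stop_validation("a sample has constant values; ranks are undefined")
  qn <- limma::normalizeQuantiles(merged, ties = TRUE)
  n1 <- ncol(d$platform1)
  replace_values(d, qn[, seq_len(n1), drop = FALSE],
                 qn[, -seq_len(n1), drop = FALSE])
}

#' @noRd
check_continuous <- function(d) {
  if (isTRUE(d$discrete))
    stop_validation("method requires continuous (non-discretized) data")
}

#' @noRd
reference_side <- function(d, reference_platform) {
  if (!(reference_platform %in% d$platforms))
    stop_validation("unknown platform label '", reference_platform, "'")
  if (reference_platform == d$platforms[1L]) c(1L, 2L) else c(2L, 1L)
}

#' Median rank scores normalization
#'
#' The reference distribution is the per-rank median across the reference
#' platform's samples (each sorted); every sample of the other platform is
#' mapped rank-to-reference-value. The reference platform is left untouched.
#'
#' @param d A `combined_dataset`.
#' @param reference_platform Platform label to use as the reference.
#' @return The normalized `combined_dataset`.
#' @export
mrs <- function(d, reference_platform = d$platforms[1L]) {
  side <- reference_side(d, reference_platform)
  ref_mat <- unclass(d[[side[1L]]])
  qry_mat <- unclass(d[[side[2L]]])
  reference <- rank_summary(ref_mat, "median")
  qry_new <- apply(qry_mat, 2L, map_to_reference, reference = reference)
  qry_new <- matrix(qry_new, nrow = nrow(qry_mat), dimnames = dimnames(qry_mat))
  vals <- list(NULL, NULL)
  vals[[side[1L]]] <- ref_mat
  vals[[side[2L]]] <- qry_new
  replace_values(d, vals[[1L]], vals[[2L]])
}

#' Gene quantiles normalization
#'
#' Two steps: first [mrs()], then a per-gene median alignment — the second
#' platform's per-gene median is subtracted and the first platform's added, so
#' that afterwards each gene has the same median expression on both platforms.
#'
#' @inheritParams mrs
#' @return The normalized `combined_dataset`.
#' @export
gq <- function(d, reference_platform = d$platforms[1L]) {
  check_continuous(d)
  side <- reference_side(d, reference_platform)
  d <- mrs(d, reference_platform)
  med_ref <- apply(unclass(d[[side[1L]]]), 1L, stats::median)
  med_qry <- apply(unclass(d[[side[2L]]]), 1L, stats::median)
  vals <- list(unclass(d$platform1), unclass(d$platform2))
  vals[[side[2L]]] <- vals[[side[2L]]] - med_qry + med_ref
  replace_values(d, vals[[1L]], vals[[2L]])
}

#' Quantile discretization
#'
#' Within each sample, values are partitioned by rank into `bins`
#' equiprobable groups and replaced by centered bin codes
#' (bin index minus `(bins + 1)/2`), so codes sum to approximately zero per
#' sample. Purely rank-based, hence identical for samples that agree up to a
#' monotone transform.
#'
#' @param d A `combined_dataset` with continuous values.
#' @param bins Number of equiprobable groups (default 8).
#' @return A discrete `combined_dataset`.
#' @export
qd <- function(d, bins = 8L) {
  check_continuous(d)
  if (bins < 2L) stop_validation("bins must be >= 2")
  if (bins > nrow(d$platform1)) stop_validation("bins exceeds gene count")
  code_sample <- function(x) {
    r <- rank(x, ties.method = "average")
    b <- pmin(pmax(ceiling(r * bins / length(x)), 1L), bins)
    b - (bins + 1) / 2
  }
  v1 <- apply(unclass(d$platform1), 2L, code_sample)
  v2 <- apply(unclass(d$platform2), 2L, code_sample)
  dimnames(v1) <- dimnames(d$platform1); dimnames(v2) <- dimnames(d$platform2)
  replace_values(d, v1, v2, discrete = TRUE)
}

#' Normal discretization (NorDi)
#'
#' Per sample: iteratively removes the most extreme value while a two-sided
#' Grubbs outlier test rejects at level `alpha`, fits a normal distribution to
#' the retained values, and codes each value +1 above the upper `1 - p`
#' normal tail, -1 below the lower tail, and 0 otherwise.
#'
#' @param d A `combined_dataset` with continuous values.
#' @param p Tail significance for the over/under-expressed calls (default 0.01).
#' @param alpha Significance level of the Grubbs outlier test (default 0.05).
#' @return A discrete `combined_dataset` with codes in \{-1, 0, +1\}.
#' @export
nordi <- function(d, p = 0.01, alpha = 0.05) {
  check_continuous(d)
  if (!(p > 0 && p < 1 && alpha > 0 && alpha < 1))
    stop_validation("p and alpha must lie in (0, 1)")
  z <- stats::qnorm(1 - p)
  code_sample <- function(x) {
    kept <- grubbs_retain(x, alpha)
    mu <- mean(kept); s <- stats::sd(kept)
    ifelse(x > mu + z * s, 1, ifelse(x < mu - z * s, -1, 0))
  }
  v1 <- apply(unclass(d$platform1), 2L, code_sample)
  v2 <- apply(unclass(d$platform2), 2L, code_sample)
  dimnames(v1) <- dimnames(d$platform1); dimnames(v2) <- dimnames(d$platform2)
  replace_values(d, v1, v2, discrete = TRUE)
}

#' Iterative two-sided Grubbs outlier trimming
#'
#' Removes the most extreme value while the Grubbs statistic exceeds its
#' critical value at level `alpha`; stops when the test no longer rejects.
#' @noRd
grubbs_retain <- function(x, alpha) {
  repeat {
    n <- length(x)
    if (n < 3L) stop_validation("fewer than 3 values retained; sample too small for outlier test")
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) return(x)
    dev <- abs(x - m)
    g <- max(dev) / s
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) return(x)
    x <- x[-which.max(dev)]
  }
}

#' Distribution transformation (DisTran)
#'
#' Samples of both platforms are clustered jointly by k-means (on per-sample
#' standardized values) into `k` clusters, which stand in for the unknown
#' treatment groups. Within each cluster the per-rank mean vector is computed
#' separately for each platform, and every sample is mapped rank-to-target
#' where the target is the unweighted mean of the two platform vectors.
#' Clusterings that leave a cluster without both platforms are redrawn.
#'
#' @param d A `combined_dataset` with continuous values.
#' @param k Number of sample clusters (use the number of treatment groups).
#' @param max_retries Redraw attempts for clusterings spanning both platforms.
#' @param standardize Standardize each gene within its platform (mean 0,
#'   sd 1) before clustering, so that gene-level platform shifts cannot force
#'   the clusters to split by platform rather than by treatment.
#' @param seed RNG seed for the k-means restarts.
#' @return The normalized `combined_dataset`.
#' @export
distran <- function(d, k, max_retries = 20L, standardize = TRUE, seed = NULL) {
  check_continuous(d)
  if (k < 1L) stop_validation("k must be >= 1")
  n1 <- ncol(d$platform1); n2 <- ncol(d$platform2)
  if (min(n1, n2) < k) stop_validation("each platform needs >= k samples")
  merged <- merged_matrix(d)
  platform_of <- rep(1:2, c(n1, n2))
  feat <- if (standardize) standardize_within_platform(merged, platform_of)
          else merged
  cl <- with_seed_(seed, cluster_spanning(t(feat), k, platform_of, max_retries))
  out <- merged
  for (g in seq_len(k)) {
    idx1 <- which(cl == g & platform_of == 1L)
    idx2 <- which(cl == g & platform_of == 2L)
    t1 <- rank_summary(merged[, idx1, drop = FALSE], "mean")
    t2 <- rank_summary(merged[, idx2, drop = FALSE], "mean")
    target <- (t1 + t2) / 2
    for (j in c(idx1, idx2)) out[, j] <- map_to_reference(merged[, j], target)
  }
  replace_values(d, out[, seq_len(n1), drop = FALSE], out[, -seq_len(n1), drop = FALSE])
}

#' Standardize each gene within its platform (clustering feature space)
#' @noRd
standardize_within_platform <- function(merged, platform_of) {
  std <- merged
  for (p in 1:2) {
    mp <- merged[, platform_of == p, drop = FALSE]
    sdv <- apply(mp, 1L, stats::sd)
    std[, platform_of == p] <- (mp - rowMeans(mp)) / ifelse(sdv > 0, sdv, 1)
  }
  std
}

#' k-means over samples, redrawn until every cluster spans both platforms
#' @noRd
cluster_spanning <- function(points, k, platform_of, max_retries) {
  if (k == 1L) return(rep(1L, nrow(points)))
  for (attempt in seq_len(max_retries)) {
    km <- stats::kmeans(points, centers = k, nstart = 10L)
    ok <- all(vapply(seq_len(k), function(g) {
      length(unique(platform_of[km$cluster == g])) == 2L
    }, logical(1L)))
    if (ok) return(km$cluster)
  }
  stop("no clustering with both platforms in every cluster found after ",
       max_retries, " attempts; consider a smaller k")
}
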
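# Model-based normalization: parametric empirical Bayes batch adjustment and
# the XPN block-model method with joint or per-platform ("modified")
# sample clustering.

#' Parametric empirical Bayes cross-platform adjustment
#'
#' ComBat-style batch adjustment treating the two platforms as batches, with
#' parametric priors (normal on batch means, inverse-gamma on batch
#' variances) and no covariates. Data are standardized per gene by the grand
#' mean and pooled within-platform scale; platform means and variances are
#' shrunk towards their prior means by iterating the coupled posterior
#' updates to convergence, and values are reconstructed on the original
#' scale.
#'
#' @param d A `combined_dataset` with continuous values and at least two
#'   samples per platform.
#' @param tol Convergence tolerance on the posterior updates (max absolute
#'   change).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return The adjusted `combined_dataset`.
#' @export
eb_adjust <- function(d, tol = 1e-4, max_iter = 500L) {
  check_continuous(d)
  n1 <- ncol(d$platform1); n2 <- ncol(d$platform2)
  if (min(n1, n2) < 2L) stop_validation("each platform needs >= 2 samples")
  y <- merged_matrix(d)
  idx <- list(seq_len(n1), n1 + seq_len(n2))
  alpha <- rowMeans(y)
  # pooled scale: residual variance after removing per-platform gene means
  resid2 <- 0
  for (i in 1:2) {
    yi <- y[, idx[[i]], drop = FALSE]
    resid2 <- resid2 + rowSums((yi - rowMeans(yi))^2)
  }
  sigma <- sqrt(resid2 / (n1 + n2))
  if (any(sigma == 0)) stop_validation("zero-variance gene(s); cannot standardize")
  z <- (y - alpha) / sigma

  zstar <- y
  for (i in 1:2) {
    zi <- z[, idx[[i]], drop = FALSE]
    ni <- ncol(zi)
    gamma_hat <- rowMeans(zi)
    delta2_hat <- apply(zi, 1L, stats::var)
    # method-of-moments hyperparameters
    gbar <- mean(gamma_hat); tau2 <- stats::var(gamma_hat)
    m <- mean(delta2_hat); s2 <- stats::var(delta2_hat)
    lambda <- (2 * s2 + m^2) / s2
    theta <- (m * s2 + m^3) / s2
    post <- eb_posterior(zi, gamma_hat, delta2_hat, ni, gbar, tau2, lambda,
                         theta, tol, max_iter)
    zstar[, idx[[i]]] <- (zi - post$gamma_star) / sqrt(post$delta2_star)
  }
  out <- zstar * sigma + alpha
  replace_values(d, out[, idx[[1L]], drop = FALSE], out[, idx[[2L]], drop = FALSE])
}

#' Coupled posterior updates for one platform's batch parameters
#' @noRd
eb_posterior <- function(zi, gamma_hat, delta2_hat, ni, gbar, tau2, lambda,
                         theta, tol, max_iter) {
  g_star <- gamma_hat
  d_star <- delta2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (ni * tau2 * gamma_hat + d_star * gbar) / (ni * tau2 + d_star)
    ss <- rowSums((zi - g_new)^2)
    d_new <- (theta + 0.5 * ss) / (ni / 2 + lambda - 1)
    delta <- max(abs(g_new - g_star), abs(d_new - d_star))
    g_star <- g_new; d_star <- d_new
    if (delta < tol)
      return(list(gamma_star = g_star, delta2_star = d_star, iterations = it))
  }
  stop("empirical Bayes posterior updates did not converge after ", max_iter,
       " iterations (max residual ", format(delta), ")")
}

#' Match clusters across platforms by centroid correlation
#'
#' Greedy maximum-correlation bipartite pairing: repeatedly pairs the as-yet
#' unpaired centroid pair with the highest Pearson correlation. Centroids with
#' zero variance correlate at -Inf.
#'
#' @param centroids1,centroids2 Matrices with one centroid per row, equal row
#'   counts.
#' @return Integer vector `pairing` with `pairing[i]` the row of `centroids2`
#'   matched to row `i` of `centroids1`.
#' @export
match_clusters <- function(centroids1, centroids2) {
  k <- nrow(centroids1)
  if (nrow(centroids2) != k) stop_validation("cluster counts differ")
  cc <- matrix(-Inf, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v1 <- centroids1[i, ]; v2 <- centroids2[j, ]
    if (stats::sd(v1) > 0 && stats::sd(v2) > 0)
      cc[i, j] <- stats::cor(v1, v2)
  }
  if (all(!is.finite(cc))) stop_validation("all centroids degenerate; no pairing possible")
  pairing <- integer(k)
  for (step in seq_len(k)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, , drop = TRUE]
    pairing[best[1L]] <- best[2L]
    cc[best[1L], ] <- -Inf
    cc[, best[2L]] <- -Inf
  }
  pairing
}

#' XPN cross-platform normalization
#'
#' Repeatedly (over `iterations` random clusterings) clusters genes into `K`
#' groups and assays into `L` groups, fits the block model
#' `x_gj = A[gene block, assay block] * b_gp + c_gp + sigma_gp * eps` per
#' platform by maximum likelihood with normal residuals, replaces the
#' platform-specific sensitivities, offsets and noise scales by their
#' cross-platform averages, reconstructs each value from its standardized
#' residual, and finally averages the transformed matrices over iterations.
#'
#' Joint assay clustering redraws until every assay cluster spans both
#' platforms; with `modified = TRUE` assays are clustered per platform and
#' the clusters matched by centroid correlation ([match_clusters()]).
#'
#' @param d A `combined_dataset` with continuous values.
#' @param gene_clusters Number of gene clusters K (default 3).
#' @param assay_clusters Number of assay clusters L; defaults to the number
#'   of treatment labels in the annotation.
#' @param iterations Number of clustering iterations averaged (default 30).
#' @param modified Use per-platform assay clustering with centroid matching.
#' @param seed RNG seed.
#' @return The normalized `combined_dataset`.
#' @export
xpn_normalize <- function(d, gene_clusters = 3L, assay_clusters = NULL,
                          iterations = 30L, modified = FALSE, seed = NULL) {
  check_continuous(d)
  n1 <- ncol(d$platform1); n2 <- ncol(d$platform2)
  if (is.null(assay_clusters)) {
    trt <- unique(d$annotation$treatment)
    assay_clusters <- max(1L, length(trt))
  }
  K <- as.integer(gene_clusters); L <- as.integer(assay_clusters)
  if (K < 1L || L < 1L) stop_validation("cluster counts must be >= 1")
  if (L > min(n1, n2)) stop_validation("assay clusters exceed a platform's sample count")
  merged <- merged_matrix(d)
  platform_of <- rep(1:2, c(n1, n2))
  # cluster on gene-standardized data (per platform) so that location-type
  # platform effects cannot dominate the sample clustering
  std <- standardize_within_platform(merged, platform_of)
  acc <- with_seed_(seed, {
    total <- matrix(0, nrow(merged), ncol(merged))
    for (it in seq_len(iterations)) {
      ga <- cluster_genes(std, K)
      aa <- if (modified) cluster_assays_matched(std, L, platform_of)
            else cluster_spanning(t(std), L, platform_of, max_retries = 100L)
      total <- total + xpn_transform(merged, ga, aa, platform_of)
    }
    total / iterations
  })
  replace_values(d, acc[, seq_len(n1), drop = FALSE], acc[, -seq_len(n1), drop = FALSE])
}

#' @noRd
cluster_genes <- function(merged, K) {
  if (K == 1L) return(rep(1L, nrow(merged)))
  stats::kmeans(merged, centers = K, nstart = 5L)$cluster
}

#' Per-platform assay clustering with centroid matching
#' @noRd
cluster_assays_matched <- function(merged, L, platform_of) {
  aa <- integer(length(platform_of))
  cents <- vector("list", 2L)
  cls <- vector("list", 2L)
  for (p in 1:2) {
    pts <- t(merged[, platform_of == p, drop = FALSE])
    if (L == 1L) {
      cls[[p]] <- rep(1L, nrow(pts)); cents[[p]] <- matrix(colMeans(pts), 1L)
    } else {
      km <- stats::kmeans(pts, centers = L, nstart = 10L)
      cls[[p]] <- km$cluster; cents[[p]] <- km$centers
    }
  }
  pairing <- match_clusters(cents[[1L]], cents[[2L]])
  # platform2 label l2 maps to the platform1 label i with pairing[i] == l2
  relabel <- match(seq_len(L), pairing)
  aa[platform_of == 1L] <- cls[[1L]]
  aa[platform_of == 2L] <- relabel[cls[[2L]]]
  aa
}

#' One XPN block-model fit-and-transform pass
#' @noRd
xpn_transform <- function(merged, gene_cluster, assay_cluster, platform_of,
                          ll_tol = 1e-6, max_inner = 200L) {
  G <- nrow(merged)
  K <- max(gene_cluster); L <- max(assay_cluster)
  fits <- vector("list", 2L)
  # initialize A as block means over both platforms, b = 1, c = 0
  A <- matrix(0, K, L)
  for (k in seq_len(K)) for (l in seq_len(L))
    A[k, l] <- mean(merged[gene_cluster == k, assay_cluster == l, drop = FALSE])
  b <- matrix(1, G, 2L); cc <- matrix(0, G, 2L); s2 <- matrix(1, G, 2L)
  cols <- list(which(platform_of == 1L), which(platform_of == 2L))
  ll_old <- -Inf
  for (inner in seq_len(max_inner)) {
    # (b, c, sigma) updates given A: per platform, genes grouped by gene cluster
    for (p in 1:2) {
      jp <- cols[[p]]
      a_of_sample <- assay_cluster[jp]
      x <- merged[, jp, drop = FALSE]
      for (k in seq_len(K)) {
        gk <- which(gene_cluster == k)
        a <- A[k, a_of_sample]
        va <- stats::var(a)
        xa <- x[gk, , drop = FALSE]
        mx <- rowMeans(xa)
        if (!is.finite(va) || va < 1e-12) {
          b[gk, p] <- 1
          cc[gk, p] <- mx - mean(a)
        } else {
          bb <- (xa %*% (a - mean(a))) / (va * (length(a) - 1))
          b[gk, p] <- bb
          cc[gk, p] <- mx - bb * mean(a)
        }
        res <- xa - outer(b[gk, p], a) - cc[gk, p]
        s2[gk, p] <- pmax(rowMeans(res^2), 1e-12)
      }
    }
    # A update given (b, c, sigma): weighted LS across both platforms
    for (k in seq_len(K)) {
      gk <- which(gene_cluster == k)
      for (l in seq_len(L)) {
        num <- 0; den <- 0
        for (p in 1:2) {
          jl <- cols[[p]][assay_cluster[cols[[p]]] == l]
          if (length(jl) == 0L) next
          w <- 1 / s2[gk, p]
          xm <- merged[gk, jl, drop = FALSE]
          num <- num + length(jl) * sum(w * b[gk, p] * (rowMeans(xm) - cc[gk, p]))
          den <- den + length(jl) * sum(w * b[gk, p]^2)
        }
        A[k, l] <- num / den
      }
    }
    # normal log-likelihood
    ll <- 0
    for (p in 1:2) {
      jp <- cols[[p]]
      pred <- outer(b[, p], rep(1, length(jp))) * A[gene_cluster, assay_cluster[jp]] +
        cc[, p]
      res <- merged[, jp, drop = FALSE] - pred
      ll <- ll - 0.5 * sum(log(s2[, p]) * length(jp) + rowSums(res^2) / s2[, p])
    }
    if (abs(ll - ll_old) < ll_tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  # cross-platform averaging and reconstruction from standardized residuals
  b_bar <- rowMeans(b)
  c_bar <- rowMeans(cc)
  s_bar <- sqrt(rowMeans(s2))
  out <- merged
  for (p in 1:2) {
    jp <- cols[[p]]
    Ag <- A[gene_cluster, assay_cluster[jp], drop = FALSE]
    pred <- Ag * b[, p] + cc[, p]
    eps <- (merged[, jp, drop = FALSE] - pred) / sqrt(s2[, p])
    out[, jp] <- Ag * b_bar + c_bar + s_bar * eps
  }
  out
}
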
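# Theoretical platform-effect machinery: the hybridization signal model, the
# gene-wise treatment x platform interaction ANOVA with pi0/pi1 estimation,
# the least-squares optimal location shift, and the transfer residual.

#' Equilibrium hybridization signal
#'
#' Langmuir-type model of the probe-target hybridization reaction: with label
#' intensity `I`, available probe sites `p0`, equilibrium constant ratio
#' `k_ratio = k+/k-` and initial target concentration `g0`, the measured
#' signal at equilibrium is `S = I g0 p0 k_ratio / (1 + k_ratio g0)`, linear
#' in `g0` for `k_ratio * g0 << 1` and saturating at `I * p0` for large `g0`.
#'
#' @param I Label intensity per target molecule (> 0).
#' @param p0 Available probe-site quantity (> 0).
#' @param k_ratio Equilibrium ratio `k+/k-` (> 0).
#' @param g0 Initial target concentration (> 0); vectorized.
#' @return List with `S` and `logS`
#'   (`log(g0) + log(I p0 k_ratio) - log(1 + k_ratio g0)`).
#' @export
hybridization_signal <- function(I, p0, k_ratio, g0) {
  if (any(c(I, p0, k_ratio, g0) <= 0) || any(!is.finite(c(I, p0, k_ratio, g0))))
    stop_validation("all hybridization parameters must be positive and finite")
  S <- I * g0 * p0 * k_ratio / (1 + k_ratio * g0)
  logS <- log(g0) + log(I * p0 * k_ratio) - log(1 + k_ratio * g0)
  list(S = S, logS = logS)
}

#' Ground-truth effects of the additive platform-effect model
#'
#' Container for the per-gene effects of the log-signal model
#' `y_ijk = T_i + P_j + C_ij + eps_ijk` (treatment i, platform j, repetition
#' k). By default the interaction matrix is row-centered across platforms
#' (`sum_j C_ij = 0`, row means absorbed into `T`), the identifiability
#' convention under which a constant interaction is indistinguishable from a
#' treatment effect and the transfer-residual formula is exact.
#'
#' @param T_ Numeric vector of treatment effects (length m).
#' @param P Numeric vector of platform effects (length 2).
#' @param C m x 2 interaction matrix.
#' @param n m x 2 matrix of replication counts.
#' @param sigma Replicate noise standard deviation (>= 0).
#' @param normalize Row-center `C` across platforms, absorbing its row means
#'   into `T_`.
#' @return A `platform_effect_truth` list.
#' @export
platform_effect_truth <- function(T_, P, C, n, sigma = 0, normalize = TRUE) {
  m <- length(T_)
  C <- matrix(C, m, 2L); n <- matrix(n, m, 2L)
  if (length(P) != 2L) stop_validation("exactly two platforms supported")
  if (sigma < 0) stop_validation("sigma must be >= 0")
  if (any(n < 0) || any(n != round(n))) stop_validation("replication counts must be non-negative integers")
  if (normalize) {
    rm_ <- rowMeans(C); T_ <- T_ + rm_; C <- C - rm_
  }
  structure(list(T_ = T_, P = P, C = C, n = n, sigma = sigma, m = m),
            class = "platform_effect_truth")
}

#' Gene-wise treatment x platform interaction ANOVA
#'
#' Per gene, fits the two-way fixed-effects model with interaction and
#' compares it to the additive model by an F-test, giving one p-value per
#' gene for the null hypothesis of no treatment-platform interaction
#' variation (a constant interaction is absorbed by the platform effect).
#' The design is shared across genes, so residual sums of squares are
#' computed through one QR decomposition per model.
#'
#' @param d A `combined_dataset` with >= 2 treatments on both platforms and
#'   >= 2 replicates in every treatment x platform cell.
#' @return Named vector of per-gene p-values.
#' @export
anova_interaction <- function(d) {
  ann <- d$annotation
  y <- merged_matrix(d)
  ann <- ann[colnames(y), ]
  treatment <- factor(ann$treatment)
  platform <- factor(ann$platform)
  if (nlevels(treatment) < 2L)
    stop_validation("interaction unidentifiable with a single treatment group")
  tab <- table(treatment, platform)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)[1L, ]
    stop_validation(sprintf("design cell (%s, %s) has < 2 replicates",
                            levels(treatment)[bad[1L]], levels(platform)[bad[2L]]))
  }
  X_full <- stats::model.matrix(~ treatment * platform)
  X_add <- stats::model.matrix(~ treatment + platform)
  rss <- function(X) colSums(qr.resid(qr(X), t(y))^2)
  rss_full <- rss(X_full); rss_add <- rss(X_add)
  df1 <- ncol(X_full) - ncol(X_add)
  df2 <- ncol(y) - ncol(X_full)
  if (df2 < 1L) stop_validation("no residual degrees of freedom")
  f <- ((rss_add - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  names(p) <- rownames(y)
  p
}

#' Estimate the fraction of genes with and without true effects
#'
#' `pi0` by the Storey-Tibshirani smoother (the [qvalues()] estimator);
#' `pi1 = 1 - pi0` estimates the fraction of genes for which the null (e.g.
#' no treatment-platform interaction) is false.
#'
#' @param p Vector of p-values.
#' @return List with `pi0` and `pi1`.
#' @export
estimate_pi1 <- function(p) {
  pi0 <- qvalues(p)$pi0
  list(pi0 = pi0, pi1 = 1 - pi0)
}

#' Least-squares optimal location shift for platform effects
#'
#' For the additive model, the single per-platform shift minimizing
#' `sum_ij n_ij (P_j + C_ij - eta_j)^2` is
#' `eta_j = P_j + sum_i n_ij C_ij / sum_i n_ij`. With one treatment group, or
#' with no interaction, the corrected cell means agree across platforms
#' exactly; with several treatments and interactions, a residual remains.
#'
#' @param truth A [platform_effect_truth()].
#' @return List with `eta` (length 2) and `corrected_means`, the noise-free
#'   m x 2 matrix of shifted cell means `T_i + P_j + C_ij - eta_j`.
#' @export
optimal_location_shift <- function(truth) {
  n <- truth$n
  if (any(colSums(n) == 0)) stop_validation("a platform has no replicates")
  eta <- truth$P + colSums(n * truth$C) / colSums(n)
  cell <- outer(truth$T_, truth$P, "+") + truth$C
  corrected <- sweep(cell, 2L, eta)
  list(eta = eta, corrected_means = corrected)
}

#' Residual treatment-difference after transferring a location shift
#'
#' The difference between the two treatment-group averages in a two-platform
#' dataset after applying a location shift derived from a different training
#' dataset, for equally sized groups with treatment i observed on platform i
#' (the missing-group layout) and platform effects assumed uniform across
#' studies:
#' `T1 - T2 + 1/2 sum_i sum_j (-1)^(j-1) (C_ij - C_train_ij)`.
#' Matched interactions cancel, leaving exactly `T1 - T2`.
#'
#' @param truth Test-data effects ([platform_effect_truth()], m = 2).
#' @param truth_train Training-data effects (m = 2) whose shift is applied.
#' @return The residual group-mean difference (scalar).
#' @export
residual_difference <- function(truth, truth_train) {
  if (truth$m != 2L || truth_train$m != 2L)
    stop_validation("residual difference is defined for m = 2 treatments")
  signs <- matrix(c(1, 1, -1, -1), 2L, 2L)  # (-1)^(j-1) over columns j
  dT <- truth$T_[1L] - truth$T_[2L]
  dT + 0.5 * sum(signs * (truth$C - truth_train$C))
}
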
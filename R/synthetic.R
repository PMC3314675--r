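# Synthetic two-platform datasets with known ground truth: the additive
# linear platform-effect model, the nonlinear hybridization (saturation)
# model, and data drawn exactly from the XPN block model.

#' Build the sample annotation for a simulated two-platform design
#' @noRd
synthetic_annotation <- function(m, n_per_group, platforms = c("P1", "P2"),
                                 study = "sim") {
  treatments <- paste0("T", seq_len(m))
  rows <- list()
  for (j in 1:2) for (i in seq_len(m)) {
    nij <- n_per_group[i, j]
    if (nij == 0L) next
    ids <- sprintf("%s_%s_r%02d", platforms[j], treatments[i], seq_len(nij))
    rows[[length(rows) + 1L]] <- data.frame(sample_id = ids,
                                            platform = platforms[j],
                                            treatment = treatments[i],
                                            study = study,
                                            stringsAsFactors = FALSE)
  }
  sample_annotation(do.call(rbind, rows))
}

#' @noRd
as_group_sizes <- function(n, m) {
  if (length(n) == 1L) matrix(as.integer(n), m, 2L)
  else matrix(as.integer(n), m, 2L)
}

#' Simulate the additive linear platform-effect model
#'
#' Per gene, draws a baseline level, treatment effects (for a `de_fraction`
#' of genes), a platform location effect, and — for exactly
#' `round(interaction_fraction * genes)` genes — a double-centered
#' treatment-platform interaction, then adds Gaussian replicate noise:
#' `y = baseline + T_i + P_j + C_ij + eps`. Defaults mirror a desk-scale
#' two-platform benchmark: 2000 genes, two treatments, 15 replicates per
#' group per platform, noise sd 0.1.
#'
#' @param genes Number of genes G.
#' @param m Number of treatment groups.
#' @param n Replicates per treatment/platform cell: scalar or m x 2 matrix.
#' @param noise_sd Replicate noise standard deviation.
#' @param de_fraction Fraction of genes with treatment effects.
#' @param t_sd Standard deviation of treatment effects.
#' @param p_sd Standard deviation of per-gene platform effects.
#' @param interaction_fraction Fraction of genes with interaction effects.
#' @param c_sd Scale of interaction effects.
#' @param baseline_mean,baseline_sd Per-gene baseline level distribution
#'   (natural-log scale).
#' @param seed RNG seed.
#' @return List with `dataset` (a `combined_dataset`) and `truth`: per-gene
#'   effect arrays (`baseline`, `T_` G x m, `P` G x 2, `C` G x m x 2,
#'   `interacting`, `de`, `sigma`, `n`) plus a [platform_effect_truth()]
#'   accessor `gene_truth(g)`.
#' @export
simulate_linear <- function(genes = 2000L, m = 2L, n = 15L, noise_sd = 0.1,
                            de_fraction = 0.3, t_sd = 1, p_sd = 1,
                            interaction_fraction = 0.5, c_sd = 0.5,
                            baseline_mean = 7, baseline_sd = 1, seed = NULL) {
  if (genes < 1L || m < 1L) stop_validation("invalid configuration")
  if (any(c(de_fraction, interaction_fraction) < 0) ||
      any(c(de_fraction, interaction_fraction) > 1))
    stop_validation("fractions must lie in [0, 1]")
  if (noise_sd < 0 || t_sd < 0 || p_sd < 0 || c_sd < 0)
    stop_validation("scale parameters must be >= 0")
  nmat <- as_group_sizes(n, m)
  with_seed_(seed, {
    baseline <- stats::rnorm(genes, baseline_mean, baseline_sd)
    de <- seq_len(genes) <= round(de_fraction * genes)
    T_ <- matrix(0, genes, m)
    T_[de, ] <- stats::rnorm(sum(de) * m, 0, t_sd)
    T_ <- T_ - rowMeans(T_)
    P <- matrix(stats::rnorm(genes * 2L, 0, p_sd), genes, 2L)
    interacting <- seq_len(genes) <= round(interaction_fraction * genes)
    # double-centered m x 2 interaction: one free column, mirrored
    c_half <- matrix(0, genes, m)
    c_half[interacting, ] <- stats::rnorm(sum(interacting) * m, 0, c_sd)
    c_half <- c_half - rowMeans(c_half)   # center over treatments
    C <- array(0, dim = c(genes, m, 2L))
    C[, , 1L] <- c_half
    C[, , 2L] <- -c_half
    mats <- simulate_cells(genes, m, nmat, function(g, i, j, nij)
      baseline[g] + T_[g, i] + P[g, j] + C[g, i, j] +
        stats::rnorm(nij, 0, noise_sd))
    truth <- list(baseline = baseline, T_ = T_, P = P, C = C,
                  interacting = interacting, de = de, sigma = noise_sd,
                  n = nmat, m = m)
    truth$gene_truth <- function(g)
      platform_effect_truth(T_[g, ], P[g, ], C[g, , ], nmat, noise_sd,
                            normalize = FALSE)
    list(dataset = build_synthetic_dataset(mats, m, nmat), truth = truth)
  })
}

#' Evaluate per-cell replicate blocks and assemble platform matrices
#' @noRd
simulate_cells <- function(genes, m, nmat, cell_fun) {
  mats <- list(NULL, NULL)
  for (j in 1:2) {
    blocks <- list()
    for (i in seq_len(m)) {
      nij <- nmat[i, j]
      if (nij == 0L) next
      block <- matrix(0, genes, nij)
      for (g in seq_len(genes)) block[g, ] <- cell_fun(g, i, j, nij)
      blocks[[length(blocks) + 1L]] <- block
    }
    mats[[j]] <- do.call(cbind, blocks)
  }
  mats
}

#' @noRd
build_synthetic_dataset <- function(mats, m, nmat) {
  ann <- synthetic_annotation(m, nmat)
  genes <- sprintf("g%05d", seq_len(nrow(mats[[1L]])))
  for (j in 1:2) {
    ids <- ann$sample_id[ann$platform == c("P1", "P2")[j]]
    dimnames(mats[[j]]) <- list(genes, ids)
  }
  combined_dataset(expression_matrix(mats[[1L]]), expression_matrix(mats[[2L]]), ann)
}

#' Simulate the nonlinear hybridization (saturation) model
#'
#' Per gene and platform, draws label intensity, probe-site quantity and
#' equilibrium ratio; per treatment, multiplies the gene's baseline target
#' concentration by a fold-change (for differentially expressed genes); the
#' log-signal follows the Langmuir saturation model plus Gaussian noise.
#' Platform 1 operates in the near-linear regime and platform 2 partially
#' saturates (the chemiluminescence-vs-fluorescence contrast), so platform
#' effects are nonlinear, gene-dependent, and interact with treatment by
#' construction.
#'
#' @param genes Number of genes.
#' @param m Number of treatment groups.
#' @param n Replicates per cell: scalar or m x 2 matrix.
#' @param noise_sd Replicate noise sd on the log-signal scale.
#' @param de_fraction Fraction of genes with treatment fold-changes.
#' @param lfc_sd Standard deviation of log fold-changes.
#' @param k_ratio_range Per-platform ranges (2 x 2 matrix, rows = platforms)
#'   for the equilibrium ratio; defaults put platform 1 near-linear and
#'   platform 2 partially saturating relative to the baseline concentrations.
#' @param identical_platforms Force identical parameter draws across
#'   platforms (no platform effect; for calibration).
#' @param seed RNG seed.
#' @return List with `dataset` and `truth` (all drawn parameters).
#' @export
simulate_mechanistic <- function(genes = 2000L, m = 2L, n = 15L,
                                 noise_sd = 0.1, de_fraction = 0.3,
                                 lfc_sd = 1,
                                 k_ratio_range = rbind(c(0.005, 0.02),
                                                       c(0.5, 2)),
                                 identical_platforms = FALSE, seed = NULL) {
  if (genes < 1L || m < 1L) stop_validation("invalid configuration")
  nmat <- as_group_sizes(n, m)
  with_seed_(seed, {
    g0 <- exp(stats::rnorm(genes, 0, 1))           # baseline target concentration
    de <- seq_len(genes) <= round(de_fraction * genes)
    lfc <- matrix(0, genes, m)
    lfc[de, ] <- stats::rnorm(sum(de) * m, 0, lfc_sd)
    lfc <- lfc - rowMeans(lfc)
    draw_platform <- function(j) list(
      I = exp(stats::rnorm(genes, 0, 0.3)),
      p0 = exp(stats::rnorm(genes, 0, 0.3)),
      k = exp(stats::runif(genes, log(k_ratio_range[j, 1L]),
                           log(k_ratio_range[j, 2L]))))
    pars <- list(draw_platform(1L), draw_platform(2L))
    if (identical_platforms) pars[[2L]] <- pars[[1L]]
    mats <- simulate_cells(genes, m, nmat, function(g, i, j, nij) {
      pp <- pars[[j]]
      hybridization_signal(pp$I[g], pp$p0[g], pp$k[g],
                           g0[g] * exp(lfc[g, i]))$logS +
        stats::rnorm(nij, 0, noise_sd)
    })
    truth <- list(g0 = g0, lfc = lfc, de = de, platform_params = pars,
                  sigma = noise_sd, n = nmat, m = m)
    list(dataset = build_synthetic_dataset(mats, m, nmat), truth = truth)
  })
}

#' Simulate data exactly from the XPN generative block model
#'
#' Draws gene-cluster and assay-cluster assignments, shared block means, and
#' per-gene per-platform sensitivities, offsets and noise scales, then emits
#' `x = A[gene block, assay block] * b + c + sigma * eps`.
#'
#' @param genes Number of genes.
#' @param n Samples per platform (scalar; assays split evenly over clusters).
#' @param K Gene clusters.
#' @param L Assay clusters.
#' @param b_sd,c_sd Spread of the per-platform sensitivities (around 1) and
#'   offsets (around 0).
#' @param sigma Noise scale (common scale of the per-gene draws).
#' @param a_sd Spread of block means.
#' @param seed RNG seed.
#' @return List with `dataset` and `model` (assignments and parameters).
#' @export
simulate_xpn_model <- function(genes = 500L, n = 20L, K = 3L, L = 2L,
                               b_sd = 0.3, c_sd = 1, sigma = 0.1, a_sd = 2,
                               seed = NULL) {
  if (K < 1L || L < 1L || genes < K || n < L) stop_validation("invalid configuration")
  with_seed_(seed, {
    gene_cluster <- sort(rep_len(seq_len(K), genes))
    assay_cluster <- sort(rep_len(seq_len(L), n))   # same layout both platforms
    A <- matrix(stats::rnorm(K * L, 0, a_sd), K, L)
    b <- matrix(stats::rnorm(genes * 2L, 1, b_sd), genes, 2L)
    cc <- matrix(stats::rnorm(genes * 2L, 0, c_sd), genes, 2L)
    s <- matrix(abs(stats::rnorm(genes * 2L, sigma, sigma / 4)), genes, 2L)
    mats <- list(NULL, NULL)
    for (j in 1:2) {
      Ag <- A[gene_cluster, assay_cluster, drop = FALSE]
      eps <- matrix(stats::rnorm(genes * n), genes, n)
      mats[[j]] <- Ag * b[, j] + cc[, j] + s[, j] * eps
    }
    nmat <- matrix(0L, L, 2L)
    for (l in seq_len(L)) nmat[l, ] <- sum(assay_cluster == l)
    ds <- build_synthetic_dataset(mats, L, nmat)  # assay clusters play treatments
    model <- list(gene_cluster = gene_cluster, assay_cluster = assay_cluster,
                  A = A, b = b, c = cc, sigma = s, K = K, L = L)
    list(dataset = ds, model = model)
  })
}
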
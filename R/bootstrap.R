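# Smoothed-bootstrap benchmark: resampling with Gaussian smoothing restricted
# to treatment groups, the equal/unequal-group benchmark with positive
# (same-platform resample) and negative (no normalization) controls, and the
# missing-group transfer experiment.

#' Smoothed bootstrap resample of one platform's samples
#'
#' Per treatment group, draws the requested number of samples with
#' replacement from that group's columns and adds i.i.d. zero-centered
#' Gaussian noise (default sd 0.1) to every value. Resampling never crosses
#' treatment groups.
#'
#' @param m Genes x samples [expression_matrix()] for one platform.
#' @param annotation A [sample_annotation()] covering the samples.
#' @param sizes Named integer vector: treatment label -> number of samples to
#'   draw.
#' @param noise_sd Smoothing noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @param id_prefix Prefix for the fresh sample ids.
#' @return List with `values` (an `expression_matrix` with fresh sample ids)
#'   and `annotation` rows for the new samples.
#' @export
smoothed_resample <- function(m, annotation, sizes, noise_sd = 0.1,
                              seed = NULL, id_prefix = "bs") {
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  ann <- annotation[annotation$sample_id %in% colnames(m), ]
  platform <- unique(ann$platform)
  with_seed_(seed, {
    cols <- list(); labs <- character(0)
    for (trt in names(sizes)) {
      pool <- ann$sample_id[ann$treatment == trt]
      if (length(pool) == 0L)
        stop_validation("treatment '", trt, "' absent from platform ", platform)
      nt <- sizes[[trt]]
      if (nt == 0L) next
      cols[[length(cols) + 1L]] <- sample(pool, nt, replace = TRUE)
      labs <- c(labs, rep(trt, nt))
    }
    picked <- unlist(cols)
    vals <- unclass(m)[, picked, drop = FALSE] +
      stats::rnorm(nrow(m) * length(picked), 0, noise_sd)
    ids <- sprintf("%s_%s_%03d", id_prefix, platform, seq_along(picked))
    colnames(vals) <- ids
    new_ann <- sample_annotation(data.frame(
      sample_id = ids, platform = platform, treatment = labs,
      study = ann$study[1L], stringsAsFactors = FALSE))
    list(values = expression_matrix(vals), annotation = new_ann)
  })
}

#' Benchmark design for [run_benchmark()]
#'
#' @param sizes Named integer vector (treatment -> n) for platform 1, or a
#'   bare integer applied to every treatment group.
#' @param sizes2 Sizes for platform 2 (defaults to `sizes`).
#' @param de_groups The two treatment labels compared for differential
#'   expression (defaults to the first two labels of the dataset).
#' @param noise_sd Smoothing noise sd (default 0.1).
#' @param B Number of bootstrap replicates (default 100).
#' @param methods Normalization methods to benchmark.
#' @param controls Include `resample.1`, `resample.2` and `no.norm` controls.
#' @param xpn_iterations Clustering iterations for XPN (default 30).
#' @param xpn_gene_clusters Gene clusters for XPN (default 3).
#' @param seed RNG seed for the whole run.
#' @return A `bootstrap_design` list.
#' @export
bootstrap_design <- function(sizes = 15L, sizes2 = NULL, de_groups = NULL,
                             noise_sd = 0.1, B = 100L,
                             methods = c("dwd", "eb", "gq", "xpn", "qn",
                                         "mrs", "distran"),
                             controls = TRUE, xpn_iterations = 30L,
                             xpn_gene_clusters = 3L, seed = 1L) {
  if (B < 1L) stop_validation("B must be >= 1")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (any(unlist(c(sizes, sizes2)) < 0)) stop_validation("sizes must be >= 0")
  structure(list(sizes = sizes, sizes2 = sizes2 %||% sizes,
                 de_groups = de_groups, noise_sd = noise_sd, B = as.integer(B),
                 methods = methods, controls = controls,
                 xpn_iterations = as.integer(xpn_iterations),
                 xpn_gene_clusters = as.integer(xpn_gene_clusters),
                 seed = as.integer(seed)),
            class = "bootstrap_design")
}

#' Crossed unequal-group design
#'
#' The two treatment groups get `m_a` and `n_a` samples on platform 1 and the
#' mirrored sizes `n_a`, `m_a` on platform 2 (the crossed layout used when
#' probing robustness to unequal group sizes).
#'
#' @param m_a,n_a Sizes of the two treatment groups on platform 1.
#' @param treatments The two treatment labels.
#' @param ... Passed to [bootstrap_design()].
#' @return A `bootstrap_design`.
#' @export
unequal_design <- function(m_a, n_a, treatments = c("T1", "T2"), ...) {
  if (m_a <= 0L || n_a <= 0L)
    stop_validation("group sizes must be positive; for a fully missing group use transfer_experiment()")
  s1 <- stats::setNames(c(m_a, n_a), treatments)
  s2 <- stats::setNames(c(n_a, m_a), treatments)
  bootstrap_design(sizes = s1, sizes2 = s2, de_groups = treatments, ...)
}

#' @noRd
resolve_sizes <- function(sizes, treatments) {
  if (!is.null(names(sizes))) {
    missing_t <- setdiff(names(sizes), treatments)
    if (length(missing_t) > 0L)
      stop_validation("unknown treatment(s) in design: ", paste(missing_t, collapse = ", "))
    return(unlist(sizes))
  }
  stats::setNames(rep(as.integer(sizes), length(treatments)), treatments)
}

#' Apply one normalization method by name
#'
#' Dispatch used by the benchmark harness; `k` (treatment-group count) feeds
#' DisTran's clustering and XPN's assay clusters.
#'
#' @param d A `combined_dataset`.
#' @param method One of `"qn"`, `"mrs"`, `"gq"`, `"distran"`, `"eb"`,
#'   `"xpn"`, `"xpn_mod"`, `"dwd"`, `"no.norm"`.
#' @param k Number of treatment groups.
#' @param seed RNG seed for stochastic methods.
#' @param xpn_iterations,xpn_gene_clusters XPN settings.
#' @return The normalized `combined_dataset`.
#' @export
apply_method <- function(d, method, k = 2L, seed = NULL,
                         xpn_iterations = 30L, xpn_gene_clusters = 3L) {
  switch(method,
    qn = quantile_normalize(d),
    mrs = mrs(d),
    gq = gq(d),
    distran = distran(d, k = k, seed = seed),
    eb = eb_adjust(d),
    xpn = xpn_normalize(d, gene_clusters = xpn_gene_clusters,
                        assay_clusters = k, iterations = xpn_iterations,
                        seed = seed),
    xpn_mod = xpn_normalize(d, gene_clusters = xpn_gene_clusters,
                            assay_clusters = k, iterations = xpn_iterations,
                            modified = TRUE, seed = seed),
    dwd = dwd_normalize(d)$dataset,
    no.norm = d,
    stop_validation("unknown method '", method, "'"))
}

#' Run the smoothed-bootstrap benchmark
#'
#' Per replicate: resamples each platform by the design, applies every
#' method, and computes the concordance `r2` (averaged over treatment groups
#' present on both platforms) plus the over/under-detection areas `o` and `u`
#' against native single-platform curves built from doubled-size resamples of
#' the two differential-expression groups. Controls: `resample.1` /
#' `resample.2` treat two independent resamples of one platform as a platform
#' pair (positive control); `no.norm` is the merged data unadjusted (negative
#' control). Method failures are recorded as `NA` for that replicate; a
#' method failing in more than 20% of replicates is abandoned with a warning.
#'
#' @param d A `combined_dataset`.
#' @param design A [bootstrap_design()].
#' @return A `bootstrap_distributions` object: nested list
#'   `method -> statistic (r2, o, u) -> numeric vector of length B`.
#' @export
run_benchmark <- function(d, design) {
  treatments <- sort(unique(d$annotation$treatment))
  de_groups <- design$de_groups %||% treatments[1:2]
  if (length(de_groups) != 2L || !all(de_groups %in% treatments))
    stop_validation("de_groups must name two treatment groups of the dataset")
  sizes1 <- resolve_sizes(design$sizes, treatments)
  sizes2 <- resolve_sizes(design$sizes2, treatments)
  for (s in list(sizes1, sizes2))
    if (!all(de_groups %in% names(s)[s > 0]))
      stop_validation("both DE groups need samples on both platforms (use transfer_experiment for missing groups)")
  k <- length(unique(c(names(sizes1)[sizes1 > 0], names(sizes2)[sizes2 > 0])))
  methods <- design$methods
  all_entries <- c(methods,
                   if (design$controls) c("resample.1", "resample.2", "no.norm"))
  stats_names <- c("r2", "o", "u")
  out <- lapply(stats::setNames(all_entries, all_entries), function(m)
    lapply(stats::setNames(stats_names, stats_names), function(s)
      rep(NA_real_, design$B)))
  failures <- stats::setNames(integer(length(all_entries)), all_entries)
  abandoned <- character(0)

  double_de <- function(sizes) {
    sizes[de_groups] <- 2L * sizes[de_groups]
    sizes
  }
  ann <- d$annotation
  plats <- list(d$platform1, d$platform2)

  for (b in seq_len(design$B)) {
    seed_b <- (design$seed + 7919L * b) %% .Machine$integer.max
    rs <- with_seed_(seed_b, {
      r1 <- smoothed_resample(plats[[1L]], ann, sizes1, design$noise_sd,
                              id_prefix = sprintf("b%03d_1", b))
      r2 <- smoothed_resample(plats[[2L]], ann, sizes2, design$noise_sd,
                              id_prefix = sprintf("b%03d_2", b))
      # native curves: doubled-size single-platform resamples
      n1 <- smoothed_resample(plats[[1L]], ann, double_de(sizes1)[de_groups],
                              design$noise_sd, id_prefix = sprintf("b%03d_n1", b))
      n2 <- smoothed_resample(plats[[2L]], ann, double_de(sizes2)[de_groups],
                              design$noise_sd, id_prefix = sprintf("b%03d_n2", b))
      # positive controls: independent same-platform resample pairs
      c1 <- lapply(1:2, function(i)
        smoothed_resample(plats[[1L]], ann, sizes1, design$noise_sd,
                          id_prefix = sprintf("b%03d_c1%d", b, i)))
      c2 <- lapply(1:2, function(i)
        smoothed_resample(plats[[2L]], ann, sizes2, design$noise_sd,
                          id_prefix = sprintf("b%03d_c2%d", b, i)))
      cn1 <- lapply(1:2, function(i)
        smoothed_resample(plats[[1L]], ann, double_de(sizes1)[de_groups],
                          design$noise_sd, id_prefix = sprintf("b%03d_cn1%d", b, i)))
      cn2 <- lapply(1:2, function(i)
        smoothed_resample(plats[[2L]], ann, double_de(sizes2)[de_groups],
                          design$noise_sd, id_prefix = sprintf("b%03d_cn2%d", b, i)))
      list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, c1 = c1, c2 = c2,
           cn1 = cn1, cn2 = cn2)
    })
    cross <- combined_dataset(rs$r1$values, rs$r2$values,
                              rbind(rs$r1$annotation, rs$r2$annotation))
    q_native <- lapply(list(rs$n1, rs$n2), function(nr) native_qlist(nr, de_groups))

    for (m in methods) {
      if (m %in% abandoned) next
      res <- tryCatch({
        norm_d <- apply_method(cross, m, k = k, seed = seed_b + 1L,
                               xpn_iterations = design$xpn_iterations,
                               xpn_gene_clusters = design$xpn_gene_clusters)
        replicate_stats(norm_d, de_groups, q_native[[1L]], q_native[[2L]])
      }, error = function(e) {
        message("method ", m, " failed in replicate ", b, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) {
        failures[m] <- failures[m] + 1L
        if (failures[m] > 0.2 * design$B) {
          warning("method ", m, " failed in > 20% of replicates; abandoned")
          abandoned <- c(abandoned, m)
        }
      } else for (s in stats_names) out[[m]][[s]][b] <- res[[s]]
    }

    if (design$controls) {
      for (pc in 1:2) {
        pair <- if (pc == 1L) rs$c1 else rs$c2
        nats <- if (pc == 1L) rs$cn1 else rs$cn2
        ctrl <- control_pair_dataset(pair)
        qs <- lapply(nats, function(nr) native_qlist(nr, de_groups))
        res <- replicate_stats(ctrl, de_groups, qs[[1L]], qs[[2L]])
        for (s in stats_names) out[[paste0("resample.", pc)]][[s]][b] <- res[[s]]
      }
      res <- replicate_stats(cross, de_groups, q_native[[1L]], q_native[[2L]])
      for (s in stats_names) out[["no.norm"]][[s]][b] <- res[[s]]
    }
  }
  structure(out, class = "bootstrap_distributions", B = design$B,
            de_groups = de_groups)
}

#' Q-values for one platform's doubled-size native resample
#' @noRd
native_qlist <- function(nr, de_groups) {
  ann <- nr$annotation
  qvalues(welch_pvalues(unclass(nr$values),
                        ann$sample_id[ann$treatment == de_groups[1L]],
                        ann$sample_id[ann$treatment == de_groups[2L]]))$qvalues
}

#' Treat two same-platform resamples as a platform pair (positive control)
#' @noRd
control_pair_dataset <- function(pair) {
  a1 <- pair[[1L]]$annotation; a2 <- pair[[2L]]$annotation
  a1$platform <- paste0(a1$platform, ".a")
  a2$platform <- paste0(a2$platform, ".b")
  combined_dataset(pair[[1L]]$values, pair[[2L]]$values,
                   rbind(as.data.frame(a1), as.data.frame(a2)))
}

#' r2 / o / u for one normalized replicate
#' @noRd
replicate_stats <- function(norm_d, de_groups, q_native1, q_native2) {
  ann <- norm_d$annotation
  groups <- intersect(unique(ann$treatment[ann$platform == norm_d$platforms[1L]]),
                      unique(ann$treatment[ann$platform == norm_d$platforms[2L]]))
  r2 <- mean(vapply(groups, function(g) mean_mean_r2(norm_d, g)$r2, numeric(1L)))
  merged <- merged_matrix(norm_d)
  q_cross <- qvalues(welch_pvalues(merged,
                                   ann$sample_id[ann$treatment == de_groups[1L]],
                                   ann$sample_id[ann$treatment == de_groups[2L]]))$qvalues
  areas <- detection_areas(q_cross, q_native1, q_native2)
  list(r2 = r2, o = areas$o, u = areas$u)
}

#' Missing-group transfer experiment
#'
#' Per replicate, builds a reduced test set in which one treatment is removed
#' from each platform (so each treatment is observed on only one platform),
#' derives a DWD location shift in each requested mode, applies it, and
#' measures over/under-detection against native curves from the full test
#' data. Concordance is undefined in this layout and not reported. Modes:
#' `self.transfer` trains on the full (resampled) test data, `transfer` on
#' the training dataset, `no.transfer` on the reduced set itself (which
#' removes the treatment difference along with the platform difference), and
#' `scrambled` permutes the transferred shift (negative control).
#'
#' @param train A `combined_dataset` used as the training study (gene lists
#'   are intersected with the test set).
#' @param test A `combined_dataset`.
#' @param drop Named character vector: platform label -> treatment to remove
#'   from that platform (one per platform).
#' @param design A [bootstrap_design()]; its `sizes` apply to the test set.
#' @param modes Subset of `c("self.transfer", "transfer", "no.transfer",
#'   "scrambled")`.
#' @return A `bootstrap_distributions` with statistics `o` and `u` per mode.
#' @export
transfer_experiment <- function(train, test, drop, design,
                                modes = c("self.transfer", "transfer",
                                          "no.transfer", "scrambled")) {
  treatments <- sort(unique(test$annotation$treatment))
  if (length(treatments) < 2L)
    stop_validation("test set needs >= 2 treatment groups")
  de_groups <- design$de_groups %||% treatments[1:2]
  if (!all(test$platforms %in% names(drop)))
    stop_validation("drop must name a treatment for each platform")
  if (any(!drop %in% treatments)) stop_validation("unknown treatment in drop")
  kept1 <- setdiff(de_groups, drop[[test$platforms[1L]]])
  kept2 <- setdiff(de_groups, drop[[test$platforms[2L]]])
  if (length(kept1) == 0L || length(kept2) == 0L || identical(kept1, kept2))
    stop_validation("drop must leave each platform one distinct treatment group")
  common <- intersect(dataset_genes(train), dataset_genes(test))
  if (length(common) == 0L) stop_validation("train and test share no genes")
  train <- restrict_genes(train, common)
  test <- restrict_genes(test, common)

  sizes1 <- resolve_sizes(design$sizes, treatments)
  sizes2 <- resolve_sizes(design$sizes2, treatments)
  out <- lapply(stats::setNames(modes, modes), function(m)
    list(o = rep(NA_real_, design$B), u = rep(NA_real_, design$B)))
  ann <- test$annotation
  plats <- list(test$platform1, test$platform2)

  for (b in seq_len(design$B)) {
    seed_b <- (design$seed + 7919L * b) %% .Machine$integer.max
    rs <- with_seed_(seed_b, {
      r1 <- smoothed_resample(plats[[1L]], ann, sizes1, design$noise_sd,
                              id_prefix = sprintf("t%03d_1", b))
      r2 <- smoothed_resample(plats[[2L]], ann, sizes2, design$noise_sd,
                              id_prefix = sprintf("t%03d_2", b))
      n1 <- smoothed_resample(plats[[1L]], ann,
                              2L * sizes1[de_groups], design$noise_sd,
                              id_prefix = sprintf("t%03d_n1", b))
      n2 <- smoothed_resample(plats[[2L]], ann,
                              2L * sizes2[de_groups], design$noise_sd,
                              id_prefix = sprintf("t%03d_n2", b))
      tr1 <- smoothed_resample(train$platform1, train$annotation,
                               resolve_sizes(design$sizes,
                                             sort(unique(train$annotation$treatment))),
                               design$noise_sd, id_prefix = sprintf("t%03d_tr1", b))
      tr2 <- smoothed_resample(train$platform2, train$annotation,
                               resolve_sizes(design$sizes2,
                                             sort(unique(train$annotation$treatment))),
                               design$noise_sd, id_prefix = sprintf("t%03d_tr2", b))
      list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, tr1 = tr1, tr2 = tr2)
    })
    full_test <- combined_dataset(rs$r1$values, rs$r2$values,
                                  rbind(rs$r1$annotation, rs$r2$annotation))
    reduced <- drop_treatments(full_test, drop)
    train_b <- combined_dataset(rs$tr1$values, rs$tr2$values,
                                rbind(rs$tr1$annotation, rs$tr2$annotation))
    q_native1 <- native_qlist(rs$n1, de_groups)
    q_native2 <- native_qlist(rs$n2, de_groups)

    transfer_shift_b <- NULL
    for (mode in modes) {
      shift <- switch(mode,
        self.transfer = rename_shift(dwd_normalize(full_test)$shift, test$platforms),
        transfer = rename_shift(dwd_normalize(train_b)$shift, test$platforms),
        no.transfer = dwd_normalize(reduced)$shift,
        scrambled = {
          if (is.null(transfer_shift_b))
            transfer_shift_b <- rename_shift(dwd_normalize(train_b)$shift,
                                             test$platforms)
          scramble_shift(transfer_shift_b, seed = seed_b + 13L)
        })
      if (mode == "transfer") transfer_shift_b <- shift
      adj <- transfer_shift(shift, reduced)
      ann_r <- adj$annotation
      q_cross <- qvalues(welch_pvalues(
        merged_matrix(adj),
        ann_r$sample_id[ann_r$treatment == de_groups[1L]],
        ann_r$sample_id[ann_r$treatment == de_groups[2L]]))$qvalues
      genes_adj <- dataset_genes(adj)
      areas <- detection_areas(q_cross, q_native1[genes_adj], q_native2[genes_adj])
      out[[mode]]$o[b] <- areas$o
      out[[mode]]$u[b] <- areas$u
    }
  }
  structure(out, class = "bootstrap_distributions", B = design$B,
            de_groups = de_groups)
}

#' Restrict a combined dataset to a gene subset
#' @noRd
restrict_genes <- function(d, genes) {
  d$platform1 <- expression_matrix(unclass(d$platform1)[genes, , drop = FALSE])
  d$platform2 <- expression_matrix(unclass(d$platform2)[genes, , drop = FALSE])
  d
}

#' Relabel a shift's platform columns (training platforms -> test platforms)
#' @noRd
rename_shift <- function(shift, platforms) {
  colnames(shift$eta) <- platforms
  shift
}

#' Remove the dropped treatment's samples from each platform
#' @noRd
drop_treatments <- function(d, drop) {
  ann <- d$annotation
  keep1 <- colnames(d$platform1)[ann[colnames(d$platform1), "treatment"] !=
                                   drop[[d$platforms[1L]]]]
  keep2 <- colnames(d$platform2)[ann[colnames(d$platform2), "treatment"] !=
                                   drop[[d$platforms[2L]]]]
  combined_dataset(expression_matrix(unclass(d$platform1)[, keep1, drop = FALSE]),
                   expression_matrix(unclass(d$platform2)[, keep2, drop = FALSE]),
                   ann)
}

#' Long-format view of benchmark distributions
#'
#' @param x A `bootstrap_distributions`.
#' @return Data frame with columns method, statistic, replicate, value.
#' @export
as.data.frame.bootstrap_distributions <- function(x, ...) {
  rows <- list()
  for (m in names(x)) for (s in names(x[[m]])) {
    v <- x[[m]][[s]]
    rows[[length(rows) + 1L]] <- data.frame(method = m, statistic = s,
                                            replicate = seq_along(v), value = v,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
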
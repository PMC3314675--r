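test_that("mean-mean concordance matches direct computation and is symmetric", {
  d <- make_tiny_dataset(genes = 50L, n1 = 6L, n2 = 6L, shift = 1,
                         noise_sd = 0.4, seed = 9L)
  cs <- mean_mean_r2(d, "A")
  ann <- d$annotation
  s1 <- intersect(colnames(d$platform1), ann$sample_id[ann$treatment == "A"])
  s2 <- intersect(colnames(d$platform2), ann$sample_id[ann$treatment == "A"])
  m1 <- rowMeans(unclass(d$platform1)[, s1]); m2 <- rowMeans(unclass(d$platform2)[, s2])
  expect_equal(cs$r2, cor(m1, m2)^2)

  # symmetric in the platforms
  swapped <- combined_dataset(d$platform2, d$platform1, d$annotation)
  expect_equal(mean_mean_r2(swapped, "A")$r2, cs$r2)

  # affine relation gives r2 = 1; independent platforms give r2 ~ 0
  ps <- make_pure_shift_dataset(genes = 50L, n = 4L, eta = rnorm(50L))
  affine <- combined_dataset(
    ps$dataset$platform1,
    expression_matrix(2 * unclass(ps$dataset$platform1) + 3,
                      dataset_genes(ps$dataset),
                      colnames(ps$dataset$platform2)),
    ps$dataset$annotation)
  expect_equal(mean_mean_r2(affine, "A")$r2, 1, tolerance = 1e-12)
  indep <- make_tiny_dataset(genes = 1000L, n1 = 4L, n2 = 4L, seed = 77L)
  expect_lt(mean_mean_r2(indep, "A")$r2, 0.01)

  # missing group on one platform
  ann2 <- as.data.frame(d$annotation)
  ann2$treatment[ann2$platform == "P2"] <- "B"
  d2 <- combined_dataset(d$platform1, d$platform2, ann2)
  expect_error(mean_mean_r2(d2, "A"), "concordance undefined")
})

test_that("vectorized Welch test agrees with stats::t.test", {
  withr::with_seed(14L, {
    m <- matrix(rnorm(20 * 11), 20, 11,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:11)))
  })
  p <- welch_pvalues(m, 1:5, 6:11)
  oracle <- apply(m, 1L, function(x) t.test(x[1:5], x[6:11])$p.value)
  expect_equal(unname(p), unname(oracle), tolerance = 1e-12)

  # equal groups -> p = 1 exactly
  m2 <- cbind(m[, 1:4], m[, 1:4])
  colnames(m2) <- sprintf("t%02d", 1:8)
  expect_equal(unname(welch_pvalues(m2, 1:4, 5:8)),
               rep(1, 20L), tolerance = 1e-12)
  expect_error(welch_pvalues(m, 1L, 2:5), ">= 2 samples")
})

test_that("Welch test has power and is calibrated under the null", {
  withr::with_seed(100L, {
    a <- matrix(rnorm(100 * 10, 0), 100, 10)
    b <- matrix(rnorm(100 * 10, 3), 100, 10)
    m <- cbind(a, b)
    rownames(m) <- sprintf("g%03d", 1:100)
    colnames(m) <- sprintf("s%02d", 1:20)
    p <- welch_pvalues(m, 1:10, 11:20)
    expect_gte(sum(p < 0.01), 95L)

    null <- matrix(rnorm(10000 * 10), 10000, 10)
    rownames(null) <- sprintf("g%05d", 1:10000)
    colnames(null) <- sprintf("s%02d", 1:10)
    p0 <- welch_pvalues(null, 1:5, 6:10)
    ks <- suppressWarnings(ks.test(p0, "punif")$statistic)
    expect_lt(unname(ks), 0.02)
  })
})

test_that("q-values follow the step-down formula and estimate pi0 on null data", {
  # brute-force oracle: q_i = min over j >= i of pi0 * G * p_(j) / j
  brute_q <- function(p, pi0) {
    G <- length(p); ord <- order(p); ps <- p[ord]
    q <- vapply(seq_len(G), function(i)
      min(pi0 * G * ps[i:G] / (i:G)), numeric(1L))
    out <- numeric(G); out[ord] <- q
    out
  }
  small <- c(0.001, 0.01, 0.5)
  res <- suppressWarnings(qvalues(small))  # < 20 p-values: pi0 forced to 1
  expect_equal(res$pi0, 1)
  expect_equal(unname(res$qvalues), c(0.003, 0.015, 0.5))

  withr::with_seed(200L, {
    for (rep in 1:5) {
      p <- runif(20L)^(1.5)  # skewed 20-element lists
      res <- qvalues(p)
      expect_equal(res$qvalues, brute_q(p, res$pi0), tolerance = 1e-14)
    }
    pnull <- runif(10000L)
    expect_gte(qvalues(pnull)$pi0, 0.9)
    expect_lte(qvalues(pnull)$pi0, 1.0)
  })

  expect_equal(unique(unname(qvalues(rep(1, 100L))$qvalues)), 1)
  expect_equal(qvalues(rep(1, 100L))$pi0, 1)
})

test_that("ROC-like curves are the q-value ecdf on the 0.001 grid", {
  cv <- roc_like_curve(c(0.25, 0.75))
  expect_equal(cv$grid, seq(0, 1, by = 0.001))
  expect_equal(cv$height[cv$grid < 0.25], rep(0, sum(cv$grid < 0.25)))
  expect_equal(cv$height[cv$grid >= 0.25 & cv$grid < 0.75],
               rep(0.5, sum(cv$grid >= 0.25 & cv$grid < 0.75)))
  expect_equal(cv$height[cv$grid >= 0.75], rep(1, sum(cv$grid >= 0.75)))

  expect_equal(roc_like_curve(rep(0, 5))$height, rep(1, 1001L))
  withr::with_seed(3L, {
    h <- roc_like_curve(runif(100))$height
    expect_true(all(diff(h) >= 0))
  })
})

test_that("union/intersection combination takes gene-wise min/max", {
  q1 <- c(g1 = 0.1, g2 = 0.9); q2 <- c(g1 = 0.5, g2 = 0.2)
  expect_equal(combine_qlists(q1, q2, "union"), c(g1 = 0.1, g2 = 0.2))
  expect_equal(combine_qlists(q1, q2, "intersection"), c(g1 = 0.5, g2 = 0.9))
  expect_equal(combine_qlists(q1, q1, "union"), q1)
  expect_equal(combine_qlists(q1, q1, "intersection"), q1)
  expect_error(combine_qlists(q1, c(a = 1, b = 2)), "mismatched")
})

test_that("detection areas vanish for identical lists and match a fine-grid oracle", {
  q <- c(0.01, 0.2, 0.6)
  areas <- detection_areas(q, q, q)
  expect_equal(areas$o, 0)
  expect_equal(areas$u, 0)

  # nothing detected: no over-detection; under-detection = native intersection area
  q1 <- c(0.05, 0.3, 0.9); q2 <- c(0.1, 0.25, 0.95)
  none <- rep(1, 3L)
  areas2 <- detection_areas(none, q1, q2)
  expect_equal(areas2$o, 0)
  # u = area under the native-intersection curve; at the very last grid point
  # (FDR threshold 1) even q = 1 counts as detected, so that point drops out
  grid <- seq(0, 1, by = 0.001)
  want_u <- pracma::trapz(grid, ecdf(pmax(q1, q2))(grid) - as.numeric(grid >= 1))
  expect_equal(areas2$u, want_u, tolerance = 1e-12)

  # fine-grid Riemann oracle on random q-lists
  riemann_areas <- function(qc, qa, qb, step = 1e-5) {
    g <- seq(0, 1, by = step)
    qu <- pmin(qa, qb); qi <- pmax(qa, qb)
    h <- function(q) ecdf(q)(g)
    o <- sum((h(qc) - h(pmax(qc, qu)))[-1L]) * step
    u <- sum((h(qi) - h(pmax(qi, qc)))[-1L]) * step
    list(o = o, u = u)
  }
  withr::with_seed(404L, {
    for (rep in 1:10) {
      qc <- runif(20L); qa <- runif(20L); qb <- runif(20L)
      got <- detection_areas(qc, qa, qb)
      want <- riemann_areas(qc, qa, qb)
      expect_lt(abs(got$o - want$o), 2e-3)
      expect_lt(abs(got$u - want$u), 2e-3)
      expect_gte(got$o, 0)
      expect_gte(got$u, 0)
    }
  })
})

test_that("Brown-Forsythe test is calibrated and detects variance differences", {
  withr::with_seed(505L, {
    rejections <- 0L
    for (i in 1:100) {
      g <- list(rnorm(50), rnorm(50), rnorm(50))
      if (brown_forsythe(g)$p.value <= 0.05) rejections <- rejections + 1L
    }
    expect_lte(rejections, 10L)
    strong <- brown_forsythe(list(rnorm(50, 0, 1), rnorm(50, 0, 4)))
    expect_lt(strong$p.value, 0.01)
  })
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(brown_forsythe(same)$statistic, 0)
  expect_error(brown_forsythe(list(1:3)), ">= 2 groups")
})

test_that("method ranking orders by median and marks Mann-Whitney significance", {
  withr::with_seed(42L, {
    x <- rnorm(100); y <- rnorm(100, 0.1); z <- rnorm(100, 2)
  })
  dists <- list(a = x, b = y, c = z)
  res <- rank_methods(dists)
  want_order <- names(sort(vapply(dists, median, numeric(1L))))
  expect_equal(res$order, want_order)
  # marks agree with direct wilcox tests at alpha / n^2
  alpha <- 0.05 / 9
  expected <- vapply(1:2, function(i) {
    pv <- wilcox.test(dists[[want_order[i]]], dists[[want_order[i + 1L]]])$p.value
    if (pv < alpha) "<" else ","
  }, character(1L))
  expect_equal(res$marks, expected)

  sep <- rank_methods(list(lo = 1:10, hi = 101:110))
  expect_equal(sep$marks, "<")
  tied <- rank_methods(list(p = rep(c(1, 2), 20), q = rep(c(1, 2), 20)))
  expect_equal(tied$marks, ",")
})
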
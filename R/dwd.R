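# Distance weighted discrimination: the convex program, location-shift
# normalization, parameter transfer, the scrambled control, and parameter
# correlation.
#
# The DWD program
#   minimize  sum_i 1/r_i + C * sum_i xi_i
#   s.t.      r_i = y_i (w . x_i + beta) + xi_i,  r_i > 0, xi_i >= 0,
#             ||w||_2 <= 1
# is solved by profiling out xi: for margin u = y (w . x + beta) the optimal
# slack gives the C^1 convex DWD loss
#   V(u) = 1/u              for u >= 1/sqrt(C)
#   V(u) = 2 sqrt(C) - C u  for u <  1/sqrt(C),
# leaving a smooth convex problem over the unit ball, solved by accelerated
# projected gradient (FISTA) with backtracking to a KKT residual < 1e-6.

#' DWD loss and its derivative
#' @noRd
dwd_loss <- function(u, C) {
  u0 <- 1 / sqrt(C)
  ifelse(u >= u0, 1 / u, 2 * sqrt(C) - C * u)
}

#' @noRd
dwd_loss_grad <- function(u, C) {
  u0 <- 1 / sqrt(C)
  ifelse(u >= u0, -1 / u^2, -C)
}

#' Solve the distance weighted discrimination program
#'
#' @param points Numeric matrix, one sample per row, features (genes) in
#'   columns.
#' @param labels Vector of +1/-1 class labels, both classes present.
#' @param C Slack penalty; `"auto"` uses `100 / median(d)^2` with `d` the
#'   pairwise between-class Euclidean distances.
#' @param tol KKT residual tolerance.
#' @param max_iter Iteration cap for the projected-gradient solver.
#' @return A `dwd_model`: list with unit direction `w`, intercept `beta`,
#'   penalty `C`, the attained `objective`, and the final `kkt_residual`.
#' @export
solve_dwd <- function(points, labels, C = "auto", tol = 1e-6,
                      max_iter = 50000L) {
  X <- as.matrix(points)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop_validation("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop_validation("both classes must be present")
  if (nrow(X) < 2L) stop_validation("need >= 2 samples")
  if (identical(C, "auto")) C <- auto_penalty(X, y)
  if (!is.numeric(C) || C <= 0) stop_validation("C must be positive")

  n <- nrow(X); p <- ncol(X)
  obj <- function(w, beta) sum(dwd_loss(y * (X %*% w + beta), C))
  grad <- function(w, beta) {
    v <- dwd_loss_grad(y * (X %*% w + beta), C) * y
    list(w = drop(crossprod(X, v)), beta = sum(v))
  }
  project <- function(w) { nw <- sqrt(sum(w^2)); if (nw > 1) w / nw else w }

  w <- rep(0, p); beta <- 0
  zw <- w; zb <- beta; tk <- 1
  step <- 1 / (C * (max(colSums(X^2)) + n) + 1)
  f_old <- obj(w, beta)
  for (it in seq_len(max_iter)) {
    g <- grad(zw, zb)
    # backtracking on the FISTA majorization
    repeat {
      w_new <- project(zw - step * g$w)
      b_new <- zb - step * g$beta
      f_new <- obj(w_new, b_new)
      dw <- w_new - zw; db <- b_new - zb
      q <- obj(zw, zb) + sum(g$w * dw) + g$beta * db +
        (sum(dw^2) + db^2) / (2 * step)
      if (f_new <= q + 1e-12 * abs(q)) break
      step <- step / 2
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zw <- w_new + ((tk - 1) / t_new) * (w_new - w)
    zb <- b_new + ((tk - 1) / t_new) * (b_new - beta)
    # monotone restart
    if (f_new > f_old) { zw <- w_new; zb <- b_new; t_new <- 1 }
    w <- w_new; beta <- b_new; tk <- t_new; f_old <- min(f_old, f_new)

    if (it %% 25L == 0L || it == max_iter) {
      res <- kkt_residual(w, beta, grad)
      if (res < tol) break
      step <- step * 1.5  # allow the step to recover after backtracking
    }
  }
  res <- kkt_residual(w, beta, grad)
  if (res >= tol)
    stop("DWD solver did not reach KKT tolerance (residual ", format(res), ")")
  structure(list(w = w, beta = beta, C = C, objective = obj(w, beta),
                 kkt_residual = res, iterations = it),
            class = "dwd_model")
}

#' @noRd
kkt_residual <- function(w, beta, grad) {
  g <- grad(w, beta)
  nw <- sqrt(sum(w^2))
  if (nw < 1 - 1e-8) {
    sqrt(sum(g$w^2) + g$beta^2)
  } else {
    mu <- -sum(g$w * w)  # multiplier of the ball constraint, must be >= 0
    tangential <- g$w + mu * w
    sqrt(sum(tangential^2) + g$beta^2 + max(0, -mu)^2)
  }
}

#' Default DWD penalty: 100 over the squared median between-class distance
#' @noRd
auto_penalty <- function(X, y) {
  a <- X[y > 0, , drop = FALSE]; b <- X[y < 0, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  med <- stats::median(sqrt(pmax(d2, 0)))
  if (med == 0) return(100)
  100 / med^2
}

#' DWD cross-platform normalization
#'
#' Labels samples by platform membership, fits [solve_dwd()] on gene-centered
#' data, and removes from every sample the component of its platform's mean
#' projection along the discriminating direction: `eta_j = mu_j * w` with
#' `mu_j` the mean projection of platform `j`, and each platform-`j` sample
#' becomes `x - eta_j`.
#'
#' @param d A `combined_dataset` with continuous values, >= 2 samples per
#'   platform.
#' @param C Slack penalty, or `"auto"` (the default heuristic).
#' @return List with elements `dataset` (the adjusted `combined_dataset`) and
#'   `shift` (a `dwd_shift` recording the per-platform location vectors).
#' @export
dwd_normalize <- function(d, C = "auto") {
  check_continuous(d)
  if (min(ncol(d$platform1), ncol(d$platform2)) < 2L)
    stop_validation("each platform needs >= 2 samples")
  merged <- merged_matrix(d)
  n1 <- ncol(d$platform1)
  center <- rowMeans(merged)
  Xc <- t(merged - center)  # samples x genes, gene-centered
  y <- rep(c(1, -1), c(n1, ncol(merged) - n1))
  model <- solve_dwd(Xc, y, C = C)
  # the location shift uses the unit discriminating direction; the optimum may
  # be interior (||w|| < 1) when the platforms overlap
  wdir <- model$w / sqrt(sum(model$w^2))
  proj <- drop(Xc %*% wdir)
  mu <- c(mean(proj[y > 0]), mean(proj[y < 0]))
  eta <- cbind(mu[1L] * wdir, mu[2L] * wdir)
  colnames(eta) <- d$platforms
  rownames(eta) <- dataset_genes(d)
  shift <- dwd_shift(eta, provenance = list(platforms = d$platforms))
  list(dataset = apply_shift(d, shift), shift = shift, model = model)
}

#' Construct a DWD location-shift record
#'
#' @param eta Genes x 2 matrix of per-platform location vectors, columns
#'   named by platform label, rows by gene id.
#' @param provenance Free-form list recording how the shift was derived.
#' @return A `dwd_shift` object.
#' @export
dwd_shift <- function(eta, provenance = list()) {
  if (is.null(rownames(eta)) || is.null(colnames(eta)))
    stop_validation("eta needs gene row names and platform column names")
  if (any(!is.finite(eta))) stop_validation("non-finite shift entries")
  structure(list(eta = eta, provenance = provenance), class = "dwd_shift")
}

#' @noRd
apply_shift <- function(d, shift) {
  common <- intersect(dataset_genes(d), rownames(shift$eta))
  if (length(common) == 0L) stop_validation("no overlapping genes between shift and dataset")
  if (length(common) < nrow(d$platform1))
    message("shift restricted to ", length(common), " common genes")
  missing_p <- setdiff(d$platforms, colnames(shift$eta))
  if (length(missing_p) > 0L)
    stop_validation("platform label(s) absent from shift: ",
                    paste(missing_p, collapse = ", "))
  v1 <- unclass(d$platform1)[common, , drop = FALSE] -
    shift$eta[common, d$platforms[1L]]
  v2 <- unclass(d$platform2)[common, , drop = FALSE] -
    shift$eta[common, d$platforms[2L]]
  if (length(common) < nrow(d$platform1)) {
    d$platform1 <- expression_matrix(unclass(d$platform1)[common, , drop = FALSE])
    d$platform2 <- expression_matrix(unclass(d$platform2)[common, , drop = FALSE])
  }
  replace_values(d, v1, v2)
}

#' Apply a previously derived DWD shift to another dataset
#'
#' Subtracts `eta_j` from every sample of the matching platform, with no
#' refitting; genes are restricted to the intersection of the shift's and the
#' dataset's gene lists. This enables normalization when a treatment group is
#' missing from one platform, provided platform effects transfer between
#' studies.
#'
#' @param shift A `dwd_shift`.
#' @param d A `combined_dataset` whose platform labels appear in the shift.
#' @return The adjusted `combined_dataset`.
#' @export
transfer_shift <- function(shift, d) {
  apply_shift(d, shift)
}

#' Scramble a DWD shift (negative control)
#'
#' Permutes the entries of each platform's location vector by one shared
#' random permutation over genes, destroying gene correspondence while
#' preserving each vector's norm and the inter-platform difference structure.
#'
#' @param shift A `dwd_shift`.
#' @param seed RNG seed (fixed seed gives a reproducible permutation).
#' @return The scrambled `dwd_shift`.
#' @export
scramble_shift <- function(shift, seed = NULL) {
  perm <- with_seed_(seed, sample.int(nrow(shift$eta)))
  eta <- shift$eta[perm, , drop = FALSE]
  rownames(eta) <- rownames(shift$eta)
  shift$eta <- eta
  shift$provenance$scrambled <- TRUE
  shift
}

#' Correlation between two DWD shifts
#'
#' Pearson correlation of the per-gene inter-platform difference vectors
#' (`eta_2 - eta_1`) of the two shifts, on their common gene subset.
#'
#' @param a,b `dwd_shift` objects with overlapping gene lists.
#' @return A single correlation.
#' @export
shift_correlation <- function(a, b) {
  common <- intersect(rownames(a$eta), rownames(b$eta))
  if (length(common) == 0L) stop_validation("no common genes between shifts")
  da <- a$eta[common, 2L] - a$eta[common, 1L]
  db <- b$eta[common, 2L] - b$eta[common, 1L]
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop_validation("zero-variance shift difference; correlation undefined")
  stats::cor(da, db)
}

#' Write a DWD shift as a delimited table
#'
#' @param shift A `dwd_shift`.
#' @param path Output path; provenance keys are written as `# key=value`
#'   header lines above a TSV of `gene_id` and one `eta_` column per platform.
#' @return Invisibly, `path`.
#' @export
write_shift <- function(shift, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(shift$provenance))
    writeLines(sprintf("# %s=%s", key,
                       paste(shift$provenance[[key]], collapse = ",")), con)
  df <- data.frame(gene_id = rownames(shift$eta), shift$eta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- paste0("eta_", colnames(shift$eta))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DWD shift written by [write_shift()]
#'
#' @param path Path to the shift table.
#' @return A `dwd_shift`.
#' @export
read_shift <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  provenance <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1L]]
    provenance[[kv[1L]]] <- strsplit(kv[2L], ",", fixed = TRUE)[[1L]]
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  eta <- as.matrix(df[, -1L, drop = FALSE])
  rownames(eta) <- df$gene_id
  colnames(eta) <- sub("^eta_", "", colnames(eta))
  dwd_shift(eta, provenance)
}
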
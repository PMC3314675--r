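# Fixture builders shared across tests. Everything is generated in code.

# A small two-platform dataset with explicit values: platform2 = platform1
# plus an optional per-gene shift, plus optional noise.
make_tiny_dataset <- function(genes = 10L, n1 = 4L, n2 = 4L, shift = 0,
                              noise_sd = 0, treatments = c("A", "B"),
                              seed = 1L) {
  withr::with_seed(seed, {
    gid <- sprintf("g%03d", seq_len(genes))
    base <- matrix(rnorm(genes * n1, 7, 1), genes, n1,
                   dimnames = list(gid, paste0("s1_", seq_len(n1))))
    v2 <- matrix(rnorm(genes * n2, 7, 1), genes, n2,
                 dimnames = list(gid, paste0("s2_", seq_len(n2)))) + shift
    if (noise_sd > 0) {
      base <- base + rnorm(length(base), 0, noise_sd)
      v2 <- v2 + rnorm(length(v2), 0, noise_sd)
    }
    ann <- sample_annotation(data.frame(
      sample_id = c(colnames(base), colnames(v2)),
      platform = rep(c("P1", "P2"), c(n1, n2)),
      treatment = c(rep_len(treatments, n1), rep_len(treatments, n2)),
      stringsAsFactors = FALSE))
    combined_dataset(expression_matrix(base), expression_matrix(v2), ann)
  })
}

# Dataset where platform2 samples are exact copies of platform1 samples
# shifted by a fixed per-gene vector (noise-free location effect).
make_pure_shift_dataset <- function(genes = 20L, n = 4L, eta = NULL, seed = 2L) {
  withr::with_seed(seed, {
    gid <- sprintf("g%03d", seq_len(genes))
    v1 <- matrix(rnorm(genes * n, 7, 1), genes, n,
                 dimnames = list(gid, paste0("a", seq_len(n))))
    if (is.null(eta)) eta <- rnorm(genes, 0, 1)
    v2 <- v1 + eta
    colnames(v2) <- paste0("b", seq_len(n))
    ann <- sample_annotation(data.frame(
      sample_id = c(colnames(v1), colnames(v2)),
      platform = rep(c("P1", "P2"), each = n),
      treatment = rep(rep_len(c("A", "B"), n), 2L),
      stringsAsFactors = FALSE))
    list(dataset = combined_dataset(expression_matrix(v1),
                                    expression_matrix(v2), ann),
         eta = eta)
  })
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(unclass(a) - unclass(b))) <= tol)
}
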
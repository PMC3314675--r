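# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's RNG
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
stop_validation <- function(...) {
  stop(structure(class = c("crossnorm_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_parse <- function(...) {
  stop(structure(class = c("crossnorm_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample rank -> reference-value mapping with average-tie handling.
#'
#' Replaces each value of `x` by the reference value at its rank; tied values
#' receive the mean of the reference values their ranks span.
#' @noRd
map_to_reference <- function(x, reference) {
  n <- length(x)
  stopifnot(length(reference) == n)
  ord <- order(x)
  out <- numeric(n)
  ref <- reference  # already sorted non-decreasing
  # walk runs of ties in sorted order
  xs <- x[ord]
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1L] == xs[i]) j <- j + 1L
    out[ord[i:j]] <- mean(ref[i:j])
    i <- j + 1L
  }
  out
}

#' Per-rank summary (mean or median) of a set of samples, each sorted.
#' @noRd
rank_summary <- function(mat, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  sorted <- apply(mat, 2L, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, ncol = ncol(mat))
  if (fun == "mean") rowMeans(sorted) else apply(sorted, 1L, stats::median)
}
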
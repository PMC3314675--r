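# Independent check for the DWD solver: a general-purpose quasi-Newton
# optimizer (stats::optim, BFGS) on a spherical reparametrization of the same
# convex objective. It shares no code path with the package's
# projected-gradient solver.

dwd_objective <- function(X, y, C) {
  u0 <- 1 / sqrt(C)
  function(w, beta) {
    u <- y * (X %*% w + beta)
    sum(ifelse(u >= u0, 1 / u, 2 * sqrt(C) - C * u))
  }
}

optim_dwd_objective <- function(X, y, C, starts = 5L, seed = 1L) {
  f <- dwd_objective(X, y, C)
  p <- ncol(X)
  withr::with_seed(seed, {
    best <- Inf
    for (s in seq_len(starts)) {
      init <- c(rnorm(p), 0)
      fit <- optim(init, function(par) {
        v <- par[seq_len(p)]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-8) return(1e10)
        f(v / nv, par[p + 1L])
      }, method = "BFGS", control = list(maxit = 500L, reltol = 1e-12))
      best <- min(best, fit$value)
    }
    best
  })
}

make_axis_problem <- function(n = 10L, dim = 10L) {
  X <- matrix(0, 2L * n, dim)
  X[seq_len(n), 1L] <- 1
  X[n + seq_len(n), 1L] <- -1
  list(X = X, y = rep(c(1, -1), each = n))
}
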
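# Shared independent oracles for the test suite.

# Trapezoid integral of f over [a, b] on a fine grid, independent of the
# Simpson normalization used inside the density model.
trapz_integral <- function(f, a, b, n = 20001L) {
  g <- seq(a, b, length.out = n)
  y <- f(g)
  sum((y[-1L] + y[-n]) / 2) * (b - a) / (n - 1L)
}

# Mean and variance of a fitted density by quadrature.
density_moments <- function(model, n = 20001L) {
  g <- seq(model$domain[1L], model$domain[2L], length.out = n)
  d <- density_eval(model, g)
  w <- (model$domain[2L] - model$domain[1L]) / (n - 1L)
  dd <- d * w
  m <- sum(g * dd) / sum(dd)
  list(mean = m, var = sum((g - m)^2 * dd) / sum(dd))
}

# Moments of a histogram's binned representation.
hist_moments <- function(h) {
  m <- sum(h$midpoints * h$counts) / sum(h$counts)
  list(mean = m,
       var = sum(h$counts * (h$midpoints - m)^2) / sum(h$counts))
}

# Central finite difference of a scalar-in-matrix function.
fd_gradient <- function(fn, B, h = 1e-6) {
  G <- matrix(0, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) for (j in seq_len(ncol(B))) {
    Bp <- B; Bp[i, j] <- Bp[i, j] + h
    Bm <- B; Bm[i, j] <- Bm[i, j] - h
    G[i, j] <- (fn(Bp) - fn(Bm)) / (2 * h)
  }
  G
}

# Direct evaluation of the Amari index formula, written independently
# of the package implementation.
amari_by_hand <- function(P) {
  A <- abs(P); Q <- nrow(A)
  term1 <- 0; term2 <- 0
  for (i in seq_len(Q)) term1 <- term1 + sum(A[i, ]) / max(A[i, ]) - 1
  for (j in seq_len(Q)) term2 <- term2 + sum(A[, j]) / max(A[, j]) - 1
  term1 / (2 * Q) + term2 / (2 * Q)
}

# A quick non-Gaussian test mixture (uniform, Laplace-like, and
# centered-exponential sources cycled to nrow(A)), mixed by A.
toy_mixture <- function(V, A = rbind(c(2, 1), c(3, 2)), seed = 1L) {
  set.seed(seed)
  Q <- nrow(A)
  gens <- list(function(n) stats::runif(n, -sqrt(3), sqrt(3)),
               function(n) (stats::rexp(n) - stats::rexp(n)) / sqrt(2),
               function(n) stats::rexp(n) - 1)
  S <- do.call(rbind, lapply(seq_len(Q), function(q) gens[[(q - 1L) %% 3L + 1L]](V)))
  list(S = S, A = A, X = A %*% S)
}
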
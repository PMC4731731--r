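test_that("Amari distance vanishes exactly on scaled permutations and matches the formula", {
  set.seed(1)
  B <- matrix(rnorm(9), 3, 3)
  expect_equal(amari_distance(B, B), 0)
  for (rep in 1:10) {
    Q <- sample(2:4, 1)
    M <- matrix(rnorm(Q * Q), Q, Q)
    while (abs(det(M)) < 1e-3) M <- matrix(rnorm(Q * Q), Q, Q)
    perm <- diag(Q)[sample(Q), ]
    lambda <- diag(runif(Q, 0.2, 3) * sample(c(-1, 1), Q, replace = TRUE))
    expect_lt(amari_distance(M, perm %*% lambda %*% M), 1e-12)
    # symmetry of use and nonnegativity
    M2 <- matrix(rnorm(Q * Q), Q, Q)
    expect_gte(amari_distance(M, M2), 0)
  }
  # hand-derived value for the printed 2x2 example
  P <- matrix(c(1, 0, 1, 1), 2, 2)       # rows (1,1), (0,1)
  expect_equal(amari_distance(P, diag(2)), 0.5)
  expect_equal(amari_by_hand(P), 0.5)
  expect_error(amari_distance(matrix(0, 2, 2), diag(2)))
})

test_that("log-likelihood equals the brute-force double sum plus the det term", {
  set.seed(2)
  toy <- toy_mixture(200, A = matrix(c(1.5, 0.3, -0.2, 0.5, 2, 0.1, 0, -0.4, 1), 3, 3))
  X <- toy$X
  B <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  S <- B %*% X
  dens <- lapply(1:3, function(q) fit_density(S[q, ], deltas = 1))
  ll <- ica_loglik(B, X, dens)
  brute <- ncol(X) * log(abs(det(B)))
  for (v in seq_len(ncol(X))) for (q in 1:3)
    brute <- brute + log(density_eval(dens[[q]], sum(B[q, ] * X[, v])))
  expect_equal(ll, brute, tolerance = 1e-9)

  # rescaling B shifts the det term by V * Q * log|c|
  c0 <- 1.7
  ll_scaled <- ica_loglik(c0 * B, X, dens)
  manual <- brute - ncol(X) * log(abs(det(B))) +
    ncol(X) * (3 * log(c0) + log(abs(det(B))))
  dens_shift <- 0
  for (q in 1:3)
    dens_shift <- dens_shift +
      sum(log(density_eval(dens[[q]], c0 * S[q, ]))) -
      sum(log(density_eval(dens[[q]], S[q, ])))
  expect_equal(ll_scaled, manual + dens_shift, tolerance = 1e-9)

  # single-component reduction
  d1 <- dens[1]
  X1 <- matrix(S[1, ], 1)
  expect_equal(ica_loglik(matrix(1, 1, 1), X1, d1),
               sum(log(density_eval(dens[[1]], S[1, ]))))
  expect_error(ica_loglik(matrix(0, 2, 2), toy$X[1:2, ], dens[1:2]))
})

test_that("analytic gradient and Hessian match central finite differences", {
  set.seed(3)
  toy <- toy_mixture(500, A = matrix(c(2, 1, 0.5, 1, 3, -0.5, 0.2, 0.1, 1), 3, 3))
  X <- toy$X
  B <- diag(3) + 0.05 * matrix(rnorm(9), 3, 3)
  S <- B %*% X
  dens <- lapply(1:3, function(q) fit_density(S[q, ], deltas = 10))
  fn <- function(Bmat) ica_loglik(Bmat, X, dens)

  G <- ica_gradient(B, X, dens)
  Gfd <- fd_gradient(fn, B)
  expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-4)

  H <- ica_hessian(B, X, dens)
  expect_lt(max(abs(H - t(H))), 1e-8)
  # Hessian vs finite differences of the analytic gradient (row-major vec)
  h <- 1e-6
  Hfd <- matrix(0, 9, 9)
  for (q in 1:3) for (j in 1:3) {
    Bp <- B; Bp[q, j] <- Bp[q, j] + h
    Bm <- B; Bm[q, j] <- Bm[q, j] - h
    dG <- (ica_gradient(Bp, X, dens) - ica_gradient(Bm, X, dens)) / (2 * h)
    Hfd[, (q - 1) * 3 + j] <- as.vector(t(dG))
  }
  expect_lt(max(abs(H - Hfd)) / max(abs(Hfd)), 1e-4)
})

test_that("Newton step solves the quadratic model exactly and safeguards preserve ascent", {
  set.seed(4)
  toy <- toy_mixture(1000)
  X <- toy$X
  B <- diag(2)
  S <- B %*% X
  dens <- lapply(1:2, function(q) fit_density(S[q, ], deltas = 1))

  # bare update with injected derivatives lands on B - solve(H, g)
  g <- matrix(rnorm(4), 2, 2)
  H <- -crossprod(matrix(rnorm(16), 4, 4)) - diag(4)   # SPD negative curvature
  res <- newton_step(B, X, dens, gradient = g, hessian = H, safeguard = FALSE)
  expected <- B - matrix(solve(H, as.vector(t(g))), 2, 2, byrow = TRUE)
  expect_equal(res$B, expected, tolerance = 1e-10)

  # zero gradient: stationary point, B unchanged
  res0 <- newton_step(B, X, dens, gradient = matrix(0, 2, 2))
  expect_identical(res0$B, B)
  expect_identical(res0$method, "stay")

  # safeguarded step never decreases the likelihood and preserves det sign
  res1 <- newton_step(B, X, dens)
  expect_gte(res1$loglik, ica_loglik(B, X, dens) - 1e-10)
  expect_identical(sign(det(res1$B)), sign(det(B)))

  # a direction that would flip the determinant triggers halving
  gflip <- matrix(c(50, 0, 0, 50), 2, 2)  # pushes B towards -I through 0
  Hneg <- -diag(4)
  res2 <- newton_step(B, X, dens, gradient = gflip, hessian = Hneg)
  expect_identical(sign(det(res2$B)), sign(det(B)))
})

test_that("standardization scales rows to unit variance, is idempotent, and shifts the likelihood analytically", {
  set.seed(5)
  toy <- toy_mixture(800)
  X <- toy$X
  B <- matrix(c(1, 0.2, -0.3, 2), 2, 2)
  st <- standardize_sources(B, X)
  expect_equal(apply(st$S, 1, var), c(1, 1), tolerance = 1e-6)
  st2 <- standardize_sources(st$B, X)
  expect_equal(st2$B, st$B, tolerance = 1e-12)
  expect_equal(st$S, st$B %*% X)

  # row with variance 4 is divided by 2
  Xr <- matrix(rnorm(500), 1); Xr <- 2 * Xr / sd(Xr)
  str <- standardize_sources(matrix(1, 1, 1), Xr)
  expect_equal(str$B[1, 1], 0.5, tolerance = 1e-12)

  # likelihood shift decomposes into det change plus density re-evaluation
  S <- B %*% X
  dens <- lapply(1:2, function(q) fit_density(S[q, ], deltas = 1))
  sds <- apply(S, 1, sd)
  ll_before <- ica_loglik(B, X, dens)
  ll_after <- ica_loglik(st$B, X, dens)
  shift <- -ncol(X) * sum(log(sds))
  for (q in 1:2)
    shift <- shift + sum(log(density_eval(dens[[q]], S[q, ] / sds[q]))) -
      sum(log(density_eval(dens[[q]], S[q, ])))
  expect_equal(ll_after - ll_before, shift, tolerance = 1e-8)

  expect_error(standardize_sources(matrix(0, 2, 2), X), "degenerate")
})

test_that("the full fit separates a uniform/Laplace mixture almost perfectly", {
  set.seed(6)
  toy <- toy_mixture(20000, seed = 42)
  fit <- suppressWarnings(pspica(toy$X, config = ica_config(max_iter = 60)))
  expect_true(all(spatial_correlation(fit$S, toy$S) >= 0.99))
  expect_lt(amari_error(fit$B, toy$A), 0.05)
  # ascent contract: every accepted step at least matches the pre-step value
  expect_true(all(fit$loglik_trace >= fit$loglik_pre_step - 1e-8))
})

test_that("already-unmixed input stays near a scaled permutation of the identity", {
  set.seed(7)
  S <- rbind(runif(8000, -sqrt(3), sqrt(3)),
             (rexp(8000) - rexp(8000)) / sqrt(2))
  fit <- suppressWarnings(
    pspica(S, config = ica_config(max_iter = 40, init = "identity")))
  expect_lt(amari_distance(fit$B, diag(2)), 0.05)
  expect_lt(fit$amari_trace[length(fit$amari_trace)], 1e-3)
})

test_that("two Gaussian sources do not crash despite being unidentifiable", {
  set.seed(8)
  X <- matrix(c(2, 1, 1, 2), 2) %*% matrix(rnorm(2 * 4000), 2)
  fit <- suppressWarnings(pspica(X, config = ica_config(max_iter = 15)))
  expect_true(all(is.finite(fit$loglik_trace)))
  expect_true(all(is.finite(fit$B)))
})

test_that("rescaling the data rescales B inversely and leaves the sources unchanged", {
  set.seed(9)
  toy <- toy_mixture(5000, seed = 11)
  cfg <- ica_config(max_iter = 20)
  f1 <- suppressWarnings(pspica(toy$X, config = cfg))
  f2 <- suppressWarnings(pspica(3.7 * toy$X, config = cfg))
  expect_equal(f2$S, f1$S, tolerance = 1e-6)
  expect_equal(3.7 * f2$B, f1$B, tolerance = 1e-6)
})

test_that("the fit's likelihood is not beaten by a derivative-free optimizer", {
  set.seed(10)
  toy <- toy_mixture(2000, seed = 5)
  cfg <- ica_config(max_iter = 40)
  fit <- suppressWarnings(pspica(toy$X, config = cfg))
  X <- toy$X - rowMeans(toy$X)
  profile_ll <- function(b) {
    B <- matrix(b, 2, 2)
    if (abs(det(B)) < 1e-8) return(-1e10)
    st <- tryCatch(standardize_sources(B, X), error = function(e) NULL)
    if (is.null(st)) return(-1e10)
    dens <- lapply(1:2, function(q)
      fit_density(st$S[q, ], deltas = fit$deltas[q]))
    ica_loglik(st$B, X, dens)
  }
  opt <- optim(as.vector(diag(2)), profile_ll,
               control = list(fnscale = -1, maxit = 300))
  expect_gte(profile_ll(as.vector(fit$B)), opt$value - 1e-3)
})
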
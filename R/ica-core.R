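#' Configuration for the P-spline ICA fit
#'
#' @param tol Convergence threshold on the Amari step
#'   `d(B(k), B(k+1))`; the iteration stops when the step falls below it.
#' @param max_iter Maximum number of outer iterations.
#' @param bins Histogram bin count `J` passed to [build_histogram()];
#'   `NULL` uses the sample-size default (100 bins at 10,000+ samples,
#'   otherwise `max(20, ceiling(sqrt(n)))`).
#' @param n_basis,degree B-spline basis size and degree for the density
#'   fits.
#' @param delta_grid Candidate smoothing penalties; AIC selection runs
#'   once at the first iteration and the chosen penalty is then held
#'   fixed, so the objective does not drift between iterations.
#' @param epsilon_factor Histogram boundary pad as a multiple of the
#'   component's standard deviation.
#' @param min_region_size Regions smaller than this are merged into the
#'   nearest-id region before density fitting.
#' @param max_halvings Newton step halvings allowed before falling back
#'   to a gradient step.
#' @param init Initialization policy: `"auto"` runs the angular
#'   likelihood scan for two-component problems (see [scan_init()]) and
#'   compares it with the supplied or identity start by log-likelihood;
#'   `"identity"` disables the scan.  The likelihood in `B` is
#'   multimodal when sources are strongly dependent, and the scan picks
#'   the starting basin by the model's own objective.
#' @param scan_theta,scan_subsample,scan_delta Angular resolution,
#'   voxel subsample size and fixed smoothing penalty used by the
#'   initialization scan.
#' @param seed Optional integer; stored in the result for provenance
#'   (the fit itself is deterministic given its inputs).
#' @return A list of class `"ica_config"`.
#' @export
ica_config <- function(tol = 1e-6, max_iter = 200L, bins = NULL,
                       n_basis = 25L, degree = 3L,
                       delta_grid = 10^seq(-3, 3, by = 1),
                       epsilon_factor = 0.1, min_region_size = 50L,
                       max_halvings = 20L, init = c("auto", "identity"),
                       scan_theta = 24L, scan_subsample = 2000L,
                       scan_delta = 1, seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(
    list(tol = tol, max_iter = as.integer(max_iter), bins = bins,
         n_basis = as.integer(n_basis), degree = as.integer(degree),
         delta_grid = delta_grid, epsilon_factor = epsilon_factor,
         min_region_size = as.integer(min_region_size),
         max_halvings = as.integer(max_halvings),
         init = match.arg(init), scan_theta = as.integer(scan_theta),
         scan_subsample = as.integer(scan_subsample),
         scan_delta = scan_delta, seed = seed),
    class = "ica_config")
}

#' Angular likelihood scan for two-component starting values
#'
#' For `Q = 2` the unmixing matrix is, up to the row scaling that
#' standardization fixes anyway, a pair of projection directions on the
#' half-circle.  The scan fits a P-spline density (per region when a
#' parcellation is in use) to the standardized projection of a voxel
#' subsample onto each of `n_theta` equally spaced directions, caching
#' the per-direction data log-likelihood, and then scores every
#' direction pair by adding the log-determinant term in closed form.
#' The best pair is returned as a starting unmixing matrix.
#'
#' This exists because the ICA log-likelihood over `B` is multimodal
#' when the sources are strongly dependent (as region-structured sources
#' are): Newton ascent from a whitened or identity start can settle in a
#' basin well below the global one, and the scan chooses the basin by
#' the likelihood itself, using no information beyond the data.
#'
#' @param X 2 x V demeaned data matrix.
#' @param map Optional [parcellation_map()] for region densities.
#' @param config An [ica_config()]; the scan reads `scan_theta`,
#'   `scan_subsample`, `scan_delta` and the density settings.
#' @return A 2 x 2 starting unmixing matrix with unit-variance rows (on
#'   the subsample).
#' @export
scan_init <- function(X, map = NULL, config = ica_config()) {
  stopifnot(is.matrix(X), nrow(X) == 2L)
  V <- ncol(X)
  idx <- if (V > config$scan_subsample)
    unique(round(seq(1L, V, length.out = config$scan_subsample))) else seq_len(V)
  Xs <- X[, idx, drop = FALSE]
  Vs <- length(idx)
  submap <- if (!is.null(map))
    parcellation_map(map$labels[idx], min_region_size = 20L) else NULL

  # scan in whitened coordinates: there the candidate directions of a
  # near-singular mixing are well separated on the half-circle, so a
  # modest angular grid resolves them
  ei <- eigen(stats::cov(t(Xs)), symmetric = TRUE)
  W <- diag(1 / sqrt(pmax(ei$values, 1e-12)), 2L) %*% t(ei$vectors)
  Xs <- W %*% Xs

  thetas <- seq(0, pi, length.out = config$scan_theta + 1L)[seq_len(config$scan_theta)]
  C <- numeric(length(thetas))
  sds <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    b <- c(cos(thetas[i]), sin(thetas[i]))
    s <- drop(b %*% Xs)
    sds[i] <- stats::sd(s)
    s <- s / sds[i]
    C[i] <- if (is.null(submap)) {
      h <- build_histogram(s, bins = config$bins,
                           epsilon = config$epsilon_factor * stats::sd(s))
      f <- fit_pspline_density(h, n_basis = config$n_basis,
                               degree = config$degree,
                               delta = config$scan_delta)
      sum(log(density_eval(f, s)))
    } else {
      models <- fit_region_densities(s, submap, n_basis = config$n_basis,
                                     degree = config$degree,
                                     delta = config$scan_delta,
                                     epsilon_factor = config$epsilon_factor)$models
      sum(per_voxel_log_density(s, submap, models))
    }
  }
  best <- c(NA_integer_, NA_integer_); bll <- -Inf
  for (i in seq_along(thetas)) for (j in seq_along(thetas)) {
    if (j <= i) next                    # row order is an ICA indeterminacy
    dt <- abs(sin(thetas[j] - thetas[i]))
    if (dt < 1e-6) next
    ll <- C[i] + C[j] + Vs * log(dt / (sds[i] * sds[j]))
    if (ll > bll) { bll <- ll; best <- c(i, j) }
  }
  rbind(c(cos(thetas[best[1L]]), sin(thetas[best[1L]])) / sds[best[1L]],
        c(cos(thetas[best[2L]]), sin(thetas[best[2L]])) / sds[best[2L]]) %*% W
}

#' Amari distance between two invertible matrices
#'
#' `d = (1/2Q) sum_i (sum_j |P_ij| / max_j |P_ij| - 1)
#'    + (1/2Q) sum_j (sum_i |P_ij| / max_i |P_ij| - 1)` with
#' `P = B1 %*% solve(B2)`.  It is zero exactly when `P` is a scaled
#' permutation, which makes it blind to the ordering and scaling
#' indeterminacies of ICA — the property that qualifies it as a
#' convergence criterion and as a recovery error against a known mixing
#' matrix.
#'
#' @param B1,B2 Invertible square matrices of equal dimension.
#' @return Nonnegative scalar.
#' @examples
#' amari_distance(diag(3), diag(3))              # 0
#' amari_distance(matrix(c(1, 0, 1, 1), 2), diag(2))  # 0.5
#' @export
amari_distance <- function(B1, B2) {
  stopifnot(is.matrix(B1), is.matrix(B2), all(dim(B1) == dim(B2)),
            nrow(B1) == ncol(B1))
  if (abs(det(B1)) < 1e-300 || abs(det(B2)) < 1e-300)
    stop("singular matrix passed to amari_distance")
  amari_index(B1 %*% solve(B2))
}

amari_index <- function(P) {
  A <- abs(P)
  Q <- nrow(A)
  rows <- sum(rowSums(A) / apply(A, 1L, max) - 1)
  cols <- sum(colSums(A) / apply(A, 2L, max) - 1)
  (rows + cols) / (2 * Q)
}

#' Joint ICA log-likelihood
#'
#' `L(B, f) = sum_v sum_q log f_q(B[q, ] %*% X[, v]) + V log |det B|`.
#' In parcellation mode each voxel is scored under its own region's
#' density `f_{r(v), q}`.
#'
#' @param B Q x Q unmixing matrix.
#' @param X Q x V demeaned data matrix.
#' @param densities List of length Q; element q is either a single
#'   `"pspline_density"` (i.i.d. mode) or a list of region models as
#'   returned by [fit_region_densities()].
#' @param map Optional [parcellation_map()]; required when the densities
#'   are per-region.
#' @return Scalar log-likelihood (finite: densities are floored).
#' @export
ica_loglik <- function(B, X, densities, map = NULL) {
  if (abs(det(B)) < 1e-300) stop("singular unmixing matrix")
  ld <- determinant(B, logarithm = TRUE)
  S <- B %*% X
  V <- ncol(X)
  total <- V * as.numeric(ld$modulus)
  for (q in seq_len(nrow(B)))
    total <- total + sum(component_log_density(S[q, ], densities[[q]], map))
  total
}

component_log_density <- function(s, dens_q, map) {
  if (inherits(dens_q, "pspline_density")) log(density_eval(dens_q, s))
  else per_voxel_log_density(s, map, dens_q)
}

component_score <- function(s, dens_q, map, deriv = 1L) {
  if (inherits(dens_q, "pspline_density")) {
    if (deriv == 1L) score_eval(dens_q, s) else score_prime_eval(dens_q, s)
  } else {
    per_voxel_score(s, map, dens_q, deriv = deriv)
  }
}

#' Gradient and Hessian of the ICA log-likelihood in B
#'
#' Closed forms from the spline score functions:
#' `dL/dB[q, j] = sum_v psi_q(S[q, v]) X[j, v] + V * solve(B)[j, q]`,
#' where `psi_q = (log f_q)'`.  The Hessian (row-major vec ordering,
#' index `(q - 1) * Q + j`) has data curvature
#' `sum_v psi_q'(S[q, v]) X[j, v] X[j', v]` on its diagonal blocks and
#' log-det curvature `-V * Binv[j, q'] * Binv[j', q]` everywhere.
#'
#' @inheritParams ica_loglik
#' @return `ica_gradient()`: a Q x Q matrix. `ica_hessian()`: a
#'   Q^2 x Q^2 symmetric matrix.
#' @export
ica_gradient <- function(B, X, densities, map = NULL) {
  if (abs(det(B)) < 1e-300) stop("singular unmixing matrix")
  Q <- nrow(B); V <- ncol(X)
  S <- B %*% X
  Binv <- solve(B)
  G <- matrix(0, Q, Q)
  for (q in seq_len(Q)) {
    psi <- component_score(S[q, ], densities[[q]], map, deriv = 1L)
    G[q, ] <- X %*% psi
  }
  G + V * t(Binv)
}

#' @rdname ica_gradient
#' @export
ica_hessian <- function(B, X, densities, map = NULL) {
  if (abs(det(B)) < 1e-300) stop("singular unmixing matrix")
  Q <- nrow(B); V <- ncol(X)
  S <- B %*% X
  Binv <- solve(B)
  H <- matrix(0, Q * Q, Q * Q)
  # det-term curvature couples all entries
  for (q in seq_len(Q)) for (j in seq_len(Q)) {
    r1 <- (q - 1L) * Q + j
    for (q2 in seq_len(Q)) for (j2 in seq_len(Q)) {
      H[r1, (q2 - 1L) * Q + j2] <- -V * Binv[j, q2] * Binv[j2, q]
    }
  }
  # data curvature: block-diagonal in the component index
  for (q in seq_len(Q)) {
    psi1 <- component_score(S[q, ], densities[[q]], map, deriv = 2L)
    blk <- X %*% (t(X) * psi1)
    idx <- (q - 1L) * Q + seq_len(Q)
    H[idx, idx] <- H[idx, idx] + blk
  }
  (H + t(H)) / 2
}

#' Safeguarded Newton-Raphson update of the unmixing matrix
#'
#' Solves `H delta = g` (with a small ridge scaled to `trace(H)/Q^2` for
#' conditioning) and proposes `B - delta`.  Because the spline-estimated
#' scores are noisy in the tails, the raw update can overshoot: if the
#' log-likelihood drops or `det(B)` changes sign, the step is halved (up
#' to `max_halvings`), and if that still fails a scaled gradient-ascent
#' step with the same halving rule is tried.
#'
#' @inheritParams ica_loglik
#' @param config An [ica_config()].
#' @param gradient,hessian Optional precomputed derivatives (computed
#'   from the densities when omitted).
#' @param safeguard Set `FALSE` to take the raw, un-ridged Newton step
#'   with no likelihood check (used when analyzing the bare update).
#' @return List with `B` (the accepted iterate), `loglik` (its
#'   log-likelihood under the current densities), and `method`
#'   (`"newton"`, `"gradient"`, or `"stay"` when the gradient is already
#'   numerically zero).
#' @export
newton_step <- function(B, X, densities, map = NULL, config = ica_config(),
                        gradient = NULL, hessian = NULL, safeguard = TRUE) {
  Q <- nrow(B)
  g <- if (is.null(gradient)) ica_gradient(B, X, densities, map) else gradient
  ll0 <- ica_loglik(B, X, densities, map)
  if (max(abs(g)) < 1e-10)
    return(list(B = B, loglik = ll0, method = "stay"))
  H <- if (is.null(hessian)) ica_hessian(B, X, densities, map) else hessian
  if (!safeguard) {
    step <- solve(H, as.vector(t(g)))
    Bn <- B - matrix(step, Q, Q, byrow = TRUE)
    return(list(B = Bn, loglik = ica_loglik(Bn, X, densities, map),
                method = "newton"))
  }
  ridge <- 1e-8 * sum(abs(diag(H))) / (Q * Q)
  Hr <- H - ridge * diag(Q * Q)
  gv <- as.vector(t(g))                       # row-major vec, matches H
  step <- tryCatch(solve(Hr, gv), error = function(e) NULL)
  sgn0 <- sign(det(B))

  try_direction <- function(dir) {
    scale <- 1
    for (i in seq_len(config$max_halvings + 1L)) {
      Bc <- B - scale * matrix(dir, Q, Q, byrow = TRUE)
      dc <- det(Bc)
      if (is.finite(dc) && sign(dc) == sgn0 && abs(dc) > 1e-12) {
        llc <- ica_loglik(Bc, X, densities, map)
        if (is.finite(llc) && llc >= ll0 - 1e-10)
          return(list(B = Bc, loglik = llc))
      }
      scale <- scale / 2
    }
    NULL
  }

  if (!is.null(step) && all(is.finite(step))) {
    res <- try_direction(step)
    if (!is.null(res)) return(c(res, method = "newton"))
  }
  # gradient ascent fallback, scaled so the first trial moves B by ~10%
  gnorm <- sqrt(sum(gv^2))
  dir <- -gv / gnorm * 0.1 * max(sqrt(sum(B^2)), 1)
  res <- try_direction(dir)
  if (!is.null(res)) return(c(res, method = "gradient"))
  stop(sprintf(
    "no admissible Newton or gradient step found (loglik %.6g, |grad| %.3g)",
    ll0, gnorm))
}

#' Rescale components to unit variance
#'
#' Divides each row of `S = B X` by its sample standard deviation and
#' applies the same factor to the corresponding row of `B`, resolving the
#' scale indeterminacy of the model in line with the `Var(S) = 1`
#' convention.
#'
#' @inheritParams ica_loglik
#' @return List with rescaled `B` and `S`.
#' @export
standardize_sources <- function(B, X) {
  S <- B %*% X
  sds <- apply(S, 1L, stats::sd)
  if (any(!is.finite(sds)) || any(sds < 1e-12))
    stop("degenerate component: an unmixed row has (near) zero variance")
  list(B = B / sds, S = S / sds)
}

#' Fit the P-spline ICA model
#'
#' Alternates (1) `S = B X` and row standardization, (2) P-spline density
#' estimation per component — per region when a parcellation is given —
#' and (3) a safeguarded Newton-Raphson update of `B`, until the Amari
#' distance between successive iterates falls below `config$tol`.
#' Density domains are rebuilt from the current sources at every
#' iteration; the smoothing penalty is selected by AIC at the first
#' iteration and then held fixed.
#'
#' The returned components are ordered by decreasing explained variance
#' of `A[, q] %*% S[q, ]` and signed so that each source row has
#' positive skewness — a pure reporting convention on a model that is
#' order- and sign-indeterminate.
#'
#' @param X Q x V data matrix (rows are mixed signals, columns are
#'   voxels/samples).  It is demeaned internally.
#' @param parcellation Optional integer label vector of length V, or a
#'   [parcellation_map()]; turns on region-specific densities.
#' @param config An [ica_config()].
#' @param B_init Optional initial unmixing matrix (default: identity).
#' @return An object of class `"pspica_fit"`: `B`, `A = solve(B)`, `S`,
#'   `densities`, `iterations`, `converged`, `amari_trace`,
#'   `loglik_trace` (log-likelihood after each accepted step), and
#'   `loglik_pre_step` (the value before each step, under the same
#'   densities, so the ascent contract of the safeguard can be audited).
#' @examples
#' S <- rbind(runif(2000, -sqrt(3), sqrt(3)),
#'            rexp(2000) - 1)
#' X <- matrix(c(2, 3, 1, 2), 2) %*% S
#' fit <- pspica(X, config = ica_config(max_iter = 30))
#' amari_distance(fit$B %*% matrix(c(2, 3, 1, 2), 2), diag(2))
#' @export
pspica <- function(X, parcellation = NULL, config = ica_config(),
                   B_init = NULL) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (anyNA(X) || any(!is.finite(X))) stop("`X` must be finite")
  Q <- nrow(X); V <- ncol(X)
  if (V <= Q) stop("need more samples (columns) than components (rows)")
  X <- X - rowMeans(X)
  map <- NULL
  if (!is.null(parcellation)) {
    map <- if (inherits(parcellation, "parcellation_map")) parcellation
           else parcellation_map(parcellation,
                                 min_region_size = config$min_region_size)
    if (length(map$labels) != V)
      stop("parcellation length does not match the number of columns of X")
  }

  candidates <- list(if (is.null(B_init)) diag(Q) else B_init)
  if (config$init == "auto" && Q == 2L)
    candidates <- c(candidates, list(scan_init(X, map, config)))
  B <- pick_start(candidates, X, map, config)
  stopifnot(all(dim(B) == c(Q, Q)))
  if (abs(det(B)) < 1e-12) stop("initial B is singular")

  deltas <- NULL                       # per-component penalties, fixed after it. 1
  amari_trace <- numeric(0)
  ll_trace <- numeric(0)
  ll_pre <- numeric(0)
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    std <- standardize_sources(B, X)
    B <- std$B; S <- std$S

    fitted <- fit_all_densities(S, map, config, deltas)
    densities <- fitted$densities
    if (is.null(deltas)) deltas <- fitted$deltas

    ll_pre <- c(ll_pre, ica_loglik(B, X, densities, map))
    step <- newton_step(B, X, densities, map, config)
    B_new <- step$B
    ll_trace <- c(ll_trace, step$loglik)
    amari_trace <- c(amari_trace, amari_distance(B, B_new))
    B <- B_new

    if (amari_trace[iter] < config$tol) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations (last Amari step %.3g)",
                    iter, amari_trace[iter]))

  std <- standardize_sources(B, X)
  B <- std$B; S <- std$S
  ord <- order_components(B, S)
  B <- diag(ord$signs) %*% B[ord$perm, , drop = FALSE]
  S <- diag(ord$signs) %*% S[ord$perm, , drop = FALSE]
  densities <- fit_all_densities(S, map, config, deltas[ord$perm])$densities

  structure(
    list(B = B, A = solve(B), S = S, densities = densities, map = map,
         iterations = iter, converged = converged,
         amari_trace = amari_trace, loglik_trace = ll_trace,
         loglik_pre_step = ll_pre, deltas = deltas[ord$perm],
         config = config),
    class = "pspica_fit")
}

# Choose among candidate starting matrices by the model's own
# log-likelihood (densities fit at each candidate's standardized
# sources, at the scan penalty so candidates are compared like for
# like).  With a single candidate it is returned untouched.
pick_start <- function(candidates, X, map, config) {
  candidates <- Filter(function(B) is.matrix(B) && all(dim(B) == dim(candidates[[1L]])) &&
                         abs(det(B)) > 1e-12, candidates)
  if (length(candidates) == 0L) stop("no admissible starting matrix")
  if (length(candidates) == 1L) return(candidates[[1L]])
  cfg <- config; cfg$delta_grid <- config$scan_delta
  lls <- vapply(candidates, function(B) {
    st <- tryCatch(standardize_sources(B, X), error = function(e) NULL)
    if (is.null(st)) return(-Inf)
    den <- fit_all_densities(st$S, map, cfg)$densities
    ica_loglik(st$B, X, den, map)
  }, numeric(1L))
  candidates[[which.max(lls)]]
}

fit_all_densities <- function(S, map, config, deltas = NULL) {
  Q <- nrow(S)
  out <- vector("list", Q)
  chosen <- numeric(Q)
  for (q in seq_len(Q)) {
    d_q <- if (is.null(deltas)) NULL else deltas[q]
    if (is.null(map)) {
      h <- build_histogram(S[q, ], bins = config$bins,
                           epsilon = config$epsilon_factor * stats::sd(S[q, ]))
      if (is.null(d_q))
        d_q <- select_penalty(h, config$delta_grid,
                              n_basis = config$n_basis,
                              degree = config$degree)$delta
      out[[q]] <- fit_pspline_density(h, n_basis = config$n_basis,
                                      degree = config$degree, delta = d_q)
    } else {
      fitted <- fit_region_densities(S[q, ], map,
                                     n_basis = config$n_basis,
                                     degree = config$degree,
                                     delta = d_q,
                                     delta_grid = config$delta_grid,
                                     epsilon_factor = config$epsilon_factor)
      out[[q]] <- fitted$models
      d_q <- fitted$delta
    }
    chosen[q] <- d_q
  }
  list(densities = out, deltas = chosen)
}

# Reporting order: decreasing explained variance of A[, q] S[q, ]; sign
# so each row has positive skewness (fallback: positive max-abs value).
order_components <- function(B, S) {
  A <- solve(B)
  ev <- colSums(A^2) * apply(S, 1L, stats::var)
  perm <- order(ev, decreasing = TRUE)
  signs <- vapply(perm, function(q) {
    s <- S[q, ]
    sk <- mean((s - mean(s))^3)
    if (abs(sk) > 1e-8) sign(sk) else sign(s[which.max(abs(s))])
  }, numeric(1L))
  signs[signs == 0] <- 1
  list(perm = perm, signs = signs)
}

#' @export
print.pspica_fit <- function(x, ...) {
  cat(sprintf(
    "P-spline ICA fit: Q = %d components, V = %d samples\n%s after %d iterations (final Amari step %.3g)\n",
    nrow(x$S), ncol(x$S),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$amari_trace[length(x$amari_trace)]))
  if (!is.null(x$map))
    cat(sprintf("parcellation: %d regions\n", x$map$n_regions))
  invisible(x)
}
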
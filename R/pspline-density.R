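#' Equidistant histogram with padded boundaries
#'
#' Bins a sample into `bins` equal-width intervals spanning
#' `[min(x) - epsilon, max(x) + epsilon]`.  The boundary pad `epsilon`
#' keeps the extreme observations away from the domain edges, where the
#' exponential-spline density model would otherwise be poorly determined.
#' Bins are half-open on the left, `(c[j-1], c[j]]`, so a value landing
#' exactly on an interior cutpoint is counted in the bin to its left.
#'
#' @param x Numeric sample (length >= 2, non-constant).
#' @param bins Number of bins `J` (>= 4).  Default: 100 when
#'   `length(x) >= 10000`, otherwise `max(20, ceiling(sqrt(length(x))))`.
#' @param epsilon Positive boundary pad, in the units of `x`.
#'   Default `0.1 * sd(x)`.
#' @return An object of class `"pspica_histogram"` with elements
#'   `cutpoints` (length `J + 1`), `counts`, `midpoints` (length `J`),
#'   `bin_width`, `epsilon`, and `n` (the sample size).
#' @examples
#' h <- build_histogram(rnorm(500), bins = 30)
#' sum(h$counts)  # 500
#' @export
build_histogram <- function(x, bins = NULL, epsilon = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be a finite numeric sample of length >= 2")
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("degenerate sample: all values are identical, no density can be fit")
  if (is.null(bins)) bins <- default_bins(length(x))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 4L)
    stop("`bins` must be an integer >= 4")
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(x)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("`epsilon` must be a positive number")

  cut <- seq(lo - epsilon, hi + epsilon, length.out = bins + 1L)
  # (c[j-1], c[j]] bins; every x lies strictly inside the padded range,
  # so no observation can fall outside.
  idx <- findInterval(x, cut, left.open = TRUE, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(
      cutpoints = cut,
      counts    = counts,
      midpoints = (cut[-1L] + cut[-(bins + 1L)]) / 2,
      bin_width = (cut[bins + 1L] - cut[1L]) / bins,
      epsilon   = epsilon,
      n         = length(x)
    ),
    class = "pspica_histogram"
  )
}

# Bin-count rule shared by the global and the per-region fits so that a
# single-region parcellation reproduces the global algorithm exactly.
default_bins <- function(n) {
  if (n >= 10000L) 100L else max(20L, as.integer(ceiling(sqrt(n))))
}

#' @export
print.pspica_histogram <- function(x, ...) {
  cat(sprintf(
    "Histogram: %d bins on [%.4g, %.4g], n = %d, bin width %.4g\n",
    length(x$counts), x$cutpoints[1L], x$cutpoints[length(x$cutpoints)],
    x$n, x$bin_width))
  invisible(x)
}

#' B-spline design matrix on a fixed domain
#'
#' Evaluates `n_basis` B-spline basis functions (or a derivative) with
#' equally spaced knots over `domain`.  Evaluation points outside the
#' domain are clamped to its boundary, so the basis can be queried safely
#' while an unmixing update transiently pushes values past the histogram
#' range.
#'
#' @param x Numeric evaluation points.
#' @param domain Length-2 numeric, the closed interval carrying the basis.
#' @param n_basis Number of basis functions `L` (>= degree + 2).
#' @param degree Polynomial degree of each piece (3 = cubic).
#' @param deriv Order of derivative to evaluate (0, 1 or 2).
#' @return A `length(x)` x `n_basis` dense matrix; each row of the
#'   `deriv = 0` design sums to 1 (partition of unity).
#' @export
bspline_basis <- function(x, domain, n_basis = 25L, degree = 3L, deriv = 0L) {
  stopifnot(length(domain) == 2L, domain[2L] > domain[1L])
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  if (n_basis < degree + 2L)
    stop("`n_basis` must be at least degree + 2")
  x <- pmin(pmax(as.numeric(x), domain[1L]), domain[2L])
  kn <- bspline_knots(domain, n_basis, degree)
  splines::splineDesign(kn, x, ord = degree + 1L,
                        derivs = rep.int(deriv, length(x)), outer.ok = TRUE)
}

# Uniformly spaced knots extending `degree` intervals beyond the domain
# (the Eilers-Marx convention).  Uniform spacing is what makes the
# difference penalty's null space correspond to low-order polynomials in
# s, hence what makes the fit conserve low-order histogram moments.
bspline_knots <- function(domain, n_basis, degree) {
  h <- (domain[2L] - domain[1L]) / (n_basis - degree)
  seq(domain[1L] - degree * h, by = h, length.out = n_basis + degree + 1L)
}

#' Fit a P-spline density by penalized Poisson histogram smoothing
#'
#' Models histogram bin counts as `n_j ~ Poisson(mu_j)` with
#' `log mu_j = D(m_j, ) %*% beta`, where `D` is a B-spline design evaluated
#' at the bin midpoints, and maximizes the penalized log-likelihood
#' `sum(n log mu) - sum(mu) - delta/2 * sum((diff(beta, d = 2))^2)`
#' by penalized iteratively reweighted least squares.  The fitted density
#' is the continuous interpolant `exp(spline(s))` rescaled to integrate to
#' one over the histogram domain (Simpson quadrature).
#'
#' With a cubic basis the fitted density conserves the first two empirical
#' moments of the histogram, which is what makes it usable inside a
#' maximum-likelihood ICA: the unit-variance constraint on the sources
#' survives the smoothing step.
#'
#' @param hist A `"pspica_histogram"` from [build_histogram()].
#' @param n_basis Number of B-spline basis functions `L`.
#' @param degree Spline degree (default cubic).
#' @param delta Nonnegative second-order difference penalty weight.
#' @param max_iter,tol IRLS iteration cap and gradient-norm tolerance.
#' @return An object of class `"pspline_density"`: `coefficients` (length
#'   `L`), `penalty`, `degree`, `n_basis`, `domain`, `norm_const`,
#'   `fitted_mu` (expected bin counts), `edf` (trace of the IRLS hat
#'   matrix), `deviance`, `aic`, `loglik_pen`, and the originating
#'   histogram.
#' @seealso [density_eval()], [score_eval()], [select_penalty()]
#' @export
fit_pspline_density <- function(hist, n_basis = 25L, degree = 3L, delta = 1,
                                max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(hist, "pspica_histogram"))
  if (!is.finite(delta) || delta < 0) stop("`delta` must be >= 0")
  n <- hist$counts
  if (all(n == 0L)) stop("degenerate histogram: all bin counts are zero")
  J <- length(n)
  domain <- range(hist$cutpoints)
  n_basis <- as.integer(n_basis)

  D <- bspline_basis(hist$midpoints, domain, n_basis, degree, deriv = 0L)
  P <- second_diff_penalty(n_basis)
  ridge <- 1e-10 * diag(n_basis)

  # start near the log counts: penalized WLS of log(n + 1/2) on the basis
  eta0 <- log(n + 0.5)
  beta <- solve(crossprod(D) + delta * P + ridge, crossprod(D, eta0))
  beta <- drop(beta)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    eta <- pmin(eta, 30)            # guard exp overflow on wild iterates
    mu <- exp(eta)
    grad <- drop(crossprod(D, n - mu)) - delta * drop(P %*% beta)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    W <- mu
    A <- crossprod(D, D * W) + delta * P + ridge
    beta_new <- drop(solve(A, crossprod(D, W * (eta + (n - mu) / W))))
    if (any(!is.finite(beta_new))) break
    beta <- beta_new
  }
  if (!converged) {
    eta <- pmin(drop(D %*% beta), 30)
    mu <- exp(eta)
    grad <- drop(crossprod(D, n - mu)) - delta * drop(P %*% beta)
    if (max(abs(grad)) >= 1e-4)
      stop(sprintf(
        "penalized IRLS did not converge (grad max %.3g after %d iterations)",
        max(abs(grad)), max_iter))
  }
  mu <- exp(pmin(drop(D %*% beta), 30))

  # effective degrees of freedom: trace of the penalized hat matrix
  A <- crossprod(D, D * mu) + delta * P + ridge
  edf <- sum(diag(solve(A, crossprod(D, D * mu))))
  dev <- poisson_deviance(n, mu)

  model <- structure(
    list(
      coefficients = beta,
      penalty   = delta,
      degree    = as.integer(degree),
      n_basis   = n_basis,
      domain    = domain,
      norm_const = NA_real_,
      fitted_mu = mu,
      edf       = edf,
      deviance  = dev,
      aic       = dev + 2 * edf,
      converged = converged,
      hist      = hist
    ),
    class = "pspline_density"
  )
  model$norm_const <- spline_exp_integral(model)
  model
}

second_diff_penalty <- function(L) {
  if (L < 3L) return(matrix(0, L, L))
  Dm <- diff(diag(L), differences = 2L)   # (L-2) x L
  crossprod(Dm)
}

poisson_deviance <- function(n, mu) {
  term <- ifelse(n > 0, n * log(n / mu), 0)
  2 * sum(term - (n - mu))
}

# Simpson-rule integral of exp(spline) over the domain; the density is
# exp(spline) / norm_const, so it integrates to 1 by construction.
spline_exp_integral <- function(model, n_intervals = 1024L) {
  a <- model$domain[1L]; b <- model$domain[2L]
  s <- seq(a, b, length.out = n_intervals + 1L)
  g <- exp(drop(bspline_basis(s, model$domain, model$n_basis, model$degree) %*%
                  model$coefficients))
  h <- (b - a) / n_intervals
  w <- rep(c(4, 2), length.out = n_intervals - 1L)
  h / 3 * (g[1L] + g[n_intervals + 1L] + sum(w * g[2:n_intervals]))
}

#' @export
print.pspline_density <- function(x, ...) {
  cat(sprintf(
    "P-spline density: degree %d, L = %d, delta = %.4g, edf = %.2f, domain [%.4g, %.4g]\n",
    x$degree, x$n_basis, x$penalty, x$edf, x$domain[1L], x$domain[2L]))
  invisible(x)
}

#' Select the smoothing penalty by AIC
#'
#' Fits the penalized Poisson model at each candidate penalty and returns
#' the one minimizing `AIC = deviance + 2 * edf`.  Ties (within 1e-12) go
#' to the larger penalty, i.e. the smoother fit.
#'
#' @param hist A `"pspica_histogram"`.
#' @param deltas Positive candidate penalties.
#' @inheritParams fit_pspline_density
#' @return List with `delta` (the winner) and `aic` (named vector of AIC
#'   values over the candidates).
#' @export
select_penalty <- function(hist, deltas = 10^seq(-3, 3, by = 1),
                           n_basis = 25L, degree = 3L) {
  stopifnot(length(deltas) >= 1L, all(deltas >= 0))
  deltas <- sort(as.numeric(deltas))
  aic <- vapply(deltas, function(d)
    fit_pspline_density(hist, n_basis = n_basis, degree = degree,
                        delta = d)$aic, numeric(1L))
  best <- aic[1L]; pick <- deltas[1L]
  for (i in seq_along(deltas)) {
    # strictly better, or tied with a larger (smoother) delta
    if (aic[i] < best - 1e-12 ||
        (abs(aic[i] - best) <= 1e-12 && deltas[i] > pick)) {
      best <- aic[i]; pick <- deltas[i]
    }
  }
  list(delta = pick, aic = stats::setNames(aic, format(deltas)))
}

#' Evaluate a fitted P-spline density
#'
#' @param model A `"pspline_density"`.
#' @param s Numeric evaluation points.
#' @param floor Lower bound applied to the returned density so that log
#'   densities stay finite (default 1e-12).
#' @return Density values; points outside the fitted domain receive the
#'   clamped boundary value.
#' @export
density_eval <- function(model, s, floor = 1e-12) {
  stopifnot(inherits(model, "pspline_density"))
  eta <- drop(bspline_basis(s, model$domain, model$n_basis, model$degree) %*%
                model$coefficients)
  pmax(exp(eta) / model$norm_const, floor)
}

#' Score function (and its derivative) of a fitted P-spline density
#'
#' Because `log f(s) = spline(s) - log(norm_const)`, the score
#' `d/ds log f` is the analytic first derivative of the spline and needs
#' no quadrature; likewise the second derivative.  Outside the fitted
#' domain the density is clamped to its boundary value, so both
#' derivatives are defined as 0 there.
#'
#' @inheritParams density_eval
#' @return Numeric vector of `d/ds log f(s)` (for [score_eval()]) or
#'   `d^2/ds^2 log f(s)` (for [score_prime_eval()]).
#' @export
score_eval <- function(model, s) {
  spline_log_deriv(model, s, deriv = 1L)
}

#' @rdname score_eval
#' @export
score_prime_eval <- function(model, s) {
  spline_log_deriv(model, s, deriv = 2L)
}

spline_log_deriv <- function(model, s, deriv) {
  s <- as.numeric(s)
  out <- numeric(length(s))
  inside <- s >= model$domain[1L] & s <= model$domain[2L]
  if (any(inside)) {
    Dd <- bspline_basis(s[inside], model$domain, model$n_basis, model$degree,
                        deriv = deriv)
    out[inside] <- drop(Dd %*% model$coefficients)
  }
  out
}

#' One-call density estimate from a raw sample
#'
#' Convenience wrapper: histogram, AIC penalty selection, final fit.
#'
#' @param x Numeric sample.
#' @param bins,epsilon Passed to [build_histogram()].
#' @param n_basis,degree Passed to [fit_pspline_density()].
#' @param deltas Penalty grid for [select_penalty()]; a single value skips
#'   selection.
#' @return A `"pspline_density"`.
#' @examples
#' f <- fit_density(rnorm(2000))
#' density_eval(f, 0)        # close to dnorm(0)
#' @export
fit_density <- function(x, bins = NULL, epsilon = NULL,
                        n_basis = 25L, degree = 3L,
                        deltas = 10^seq(-3, 3, by = 1)) {
  h <- build_histogram(x, bins = bins, epsilon = epsilon)
  delta <- if (length(deltas) == 1L) deltas
           else select_penalty(h, deltas, n_basis = n_basis, degree = degree)$delta
  fit_pspline_density(h, n_basis = n_basis, degree = degree, delta = delta)
}
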
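#' Remove row means
#'
#' The ICA model assumes mean-zero signals; any observed matrix is
#' centered row-wise before analysis.
#'
#' @param X Numeric matrix.
#' @return List with `X` (centered) and `offsets` (the removed row
#'   means, for reporting).
#' @export
demean <- function(X) {
  stopifnot(is.matrix(X))
  mu <- rowMeans(X)
  list(X = X - mu, offsets = mu)
}

#' Within-subject temporal SVD reduction
#'
#' Computes the economy SVD `X = U D t(V)` of one subject's T x V matrix
#' and retains the first `R` principal-component score rows `D[1:R] *
#' t(V[, 1:R])`, i.e. the best rank-R summary of the voxel-domain
#' structure (Eckart-Young).  The row-orthonormal projection `t(U[, 1:R])`
#' that produces the scores from `X` is returned for back-reconstruction.
#' Signs follow a fixed convention (largest-magnitude loading of each
#' component positive) so runs are reproducible.
#'
#' @param X T x V subject matrix (demeaned).
#' @param R Number of components to retain, `1 <= R <= min(T, V)`.
#' @return List with `scores` (R x V), `projection` (R x T, orthonormal
#'   rows), and `d` (all singular values of `X`).
#' @export
subject_reduce <- function(X, R) {
  stopifnot(is.matrix(X))
  R <- as.integer(R)
  if (R < 1L || R > min(dim(X)))
    stop(sprintf("R must be in 1..%d", min(dim(X))))
  sv <- svd(X)
  flip <- svd_sign_flip(sv$v[, seq_len(R), drop = FALSE])
  proj <- t(sv$u[, seq_len(R), drop = FALSE] * rep(flip, each = nrow(X)))
  scores <- (sv$d[seq_len(R)] * flip) * t(sv$v[, seq_len(R), drop = FALSE])
  list(scores = scores, projection = proj, d = sv$d)
}

svd_sign_flip <- function(V) {
  vapply(seq_len(ncol(V)), function(j) {
    v <- V[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1L))
}

#' Group-level SVD reduction of stacked subject scores
#'
#' Stacks the per-subject score matrices (RI x V), retains the first `Q`
#' singular vectors, and standardizes the reduced rows to unit sample
#' variance, producing the determined Q x V system the ICA is fit to.
#'
#' @param stacked RI x V matrix of vertically stacked subject scores, or
#'   a list of score matrices to stack.
#' @param Q Number of group components, `1 <= Q <= nrow(stacked)`.
#' @return An object of class `"ica_reduction"`: `reduced` (Q x V,
#'   unit-variance rows), `group_projection` (Q x RI, orthonormal rows),
#'   `scales` (row sds removed from the raw scores), `d` (group singular
#'   values), and `explained` (cumulative variance fraction at `Q`).
#' @export
group_reduce <- function(stacked, Q) {
  if (is.list(stacked)) stacked <- do.call(rbind, stacked)
  stopifnot(is.matrix(stacked))
  Q <- as.integer(Q)
  if (Q < 1L || Q > min(dim(stacked)))
    stop(sprintf("Q must be in 1..%d", min(dim(stacked))))
  sv <- svd(stacked)
  flip <- svd_sign_flip(sv$v[, seq_len(Q), drop = FALSE])
  G <- t(sv$u[, seq_len(Q), drop = FALSE] * rep(flip, each = nrow(stacked)))
  raw <- (sv$d[seq_len(Q)] * flip) * t(sv$v[, seq_len(Q), drop = FALSE])
  scales <- apply(raw, 1L, stats::sd)
  if (any(scales < 1e-12)) stop("a retained group component has zero variance")
  structure(
    list(reduced = raw / scales, group_projection = G, scales = scales,
         d = sv$d, explained = sum(sv$d[seq_len(Q)]^2) / sum(sv$d^2)),
    class = "ica_reduction")
}

#' Two-stage reduction of a multi-subject stack
#'
#' Demeans each subject, reduces each to `R` temporal components, stacks,
#' and reduces the stack to `Q` group components.  This is the standard
#' group spatial ICA preprocessing: the first stage compresses each
#' subject's scan dimension, the second forces a determined linear
#' system for the group model.
#'
#' @param subjects List of T_i x V subject matrices (common V).
#' @param Q Group components.
#' @param R Subject-level components; default `min(T, 2Q)`.
#' @return An `"ica_reduction"` augmented with `subject_projections`
#'   (list of R x T_i operators), `subject_dims` (the T_i), and `R`.
#' @export
reduce_subjects <- function(subjects, Q, R = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  V <- unique(vapply(subjects, ncol, integer(1L)))
  if (length(V) != 1L) stop("all subjects must share the same number of voxels")
  Tmin <- min(vapply(subjects, nrow, integer(1L)))
  if (is.null(R)) R <- min(Tmin, 2L * Q)
  R <- as.integer(R)
  if (R > Tmin) stop(sprintf("R = %d exceeds the shortest subject (T = %d)", R, Tmin))

  reds <- lapply(subjects, function(Xi) subject_reduce(demean(Xi)$X, R))
  red <- group_reduce(lapply(reds, `[[`, "scores"), Q)
  red$subject_projections <- lapply(reds, `[[`, "projection")
  red$subject_dims <- vapply(subjects, nrow, integer(1L))
  red$R <- R
  red
}

#' PVD-style initial unmixing matrix
#'
#' In the reduced space the population value decomposition of the data
#' is already in hand: the reduced rows are the leading singular-vector
#' scores, rescaled to unit variance.  Undoing that rescaling and the
#' singular values maps the reduced data onto the orthonormal
#' right-singular vectors — the PVD spatial factors — so the implied
#' starting unmixing matrix is diagonal:
#' `B0 = sqrt(V) * diag(scales / d[1:Q])`.  Its mixing inverse, pushed
#' back through the stored projections, is exactly the corresponding
#' block of `U D`.  With one subject the construction coincides with
#' plain SVD initialization.  A ridge perturbation guarantees
#' `det(B0) != 0` (it cannot trigger for a valid reduction, whose scales
#' are positive, but keeps the contract explicit).
#'
#' @param reduction An `"ica_reduction"`.
#' @return Q x Q initial unmixing matrix with nonzero determinant.
#' @export
initialize_unmixing <- function(reduction) {
  stopifnot(inherits(reduction, "ica_reduction"))
  Q <- nrow(reduction$reduced)
  V <- ncol(reduction$reduced)
  B0 <- sqrt(V) * diag(reduction$scales / reduction$d[seq_len(Q)], nrow = Q)
  if (abs(det(B0)) < 1e-12) B0 <- B0 + 1e-8 * diag(Q)
  B0
}

#' Back-reconstruct subject mixing matrices
#'
#' Given the group mixing matrix `A = solve(B)` estimated in the reduced
#' space, partitions the implied stacked mixing operator into its
#' per-subject blocks: `A_i = t(P_i) %*% M[block_i, ]` with
#' `M = t(G) %*% diag(scales) %*% A`, where `P_i` and `G` are the stored
#' stage-one and stage-two projections.  `A_i %*% S` approximates `X_i`
#' up to the two SVD truncation residuals.
#'
#' @param A_group Q x Q mixing matrix from the reduced-space fit.
#' @param reduction The `"ica_reduction"` from [reduce_subjects()].
#' @return List of T_i x Q subject mixing matrices.
#' @export
backreconstruct_mixing <- function(A_group, reduction) {
  stopifnot(inherits(reduction, "ica_reduction"),
            !is.null(reduction$subject_projections))
  Q <- nrow(reduction$reduced)
  stopifnot(all(dim(A_group) == c(Q, Q)))
  M <- t(reduction$group_projection) %*% (reduction$scales * A_group)
  R <- reduction$R
  lapply(seq_along(reduction$subject_projections), function(i) {
    rows <- (i - 1L) * R + seq_len(R)
    t(reduction$subject_projections[[i]]) %*% M[rows, , drop = FALSE]
  })
}

#' Group P-spline ICA
#'
#' End-to-end multi-subject fit: two-stage SVD reduction, PVD-style
#' initialization, reduced-space [pspica()] fit, and back-reconstruction
#' of the subject mixing matrices.
#'
#' @inheritParams reduce_subjects
#' @param parcellation Optional per-voxel labels for region-specific
#'   densities.
#' @param config An [ica_config()].
#' @return A `"pspica_fit"` with extra fields `reduction` and
#'   `subject_mixing` (list of T_i x Q matrices).
#' @export
group_pspica <- function(subjects, Q, R = NULL, parcellation = NULL,
                         config = ica_config()) {
  red <- reduce_subjects(subjects, Q, R)
  fit <- pspica(red$reduced, parcellation = parcellation, config = config,
                B_init = initialize_unmixing(red))
  fit$reduction <- red
  fit$subject_mixing <- backreconstruct_mixing(fit$A, red)
  fit
}
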
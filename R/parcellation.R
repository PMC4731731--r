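#' Parcellation map
#'
#' Wraps an integer region label per voxel/sample.  Labels need not be
#' contiguous; zeros and negative values are treated as "unassigned" and
#' collected into their own region.  Regions smaller than
#' `min_region_size` are merged into the region with the nearest id
#' (histogram smoothing on a handful of values is unstable), with a
#' warning naming the merged labels.
#'
#' @param labels Integer vector, one label per sample.
#' @param min_region_size Minimum samples a region must hold.
#' @return An object of class `"parcellation_map"`: `labels` (remapped
#'   to `1..n_regions`), `n_regions`, `region_sizes`, and
#'   `original_labels` (the input ids each region came from).
#' @export
parcellation_map <- function(labels, min_region_size = 50L) {
  if (is.matrix(labels)) labels <- as.vector(labels)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("parcellation labels must not contain NA")
  labels[labels <= 0L] <- 0L          # unassigned bucket

  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1L))

  # merge small regions into the nearest-id surviving region
  if (length(ids) > 1L) {
    repeat {
      small <- which(sizes < min_region_size)
      if (length(small) == 0L || length(ids) == 1L) break
      k <- small[which.min(sizes[small])]
      others <- setdiff(seq_along(ids), k)
      target <- others[which.min(abs(ids[others] - ids[k]))]
      warning(sprintf(
        "region %d (%d samples) merged into region %d (min_region_size = %d)",
        ids[k], sizes[k], ids[target], min_region_size))
      labels[labels == ids[k]] <- ids[target]
      sizes[target] <- sizes[target] + sizes[k]
      ids <- ids[-k]; sizes <- sizes[-k]
    }
  }

  remap <- match(labels, ids)
  structure(
    list(labels = remap, n_regions = length(ids),
         region_sizes = as.integer(sizes), original_labels = ids),
    class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions over %d samples (sizes %s)\n",
              x$n_regions, length(x$labels),
              paste(x$region_sizes, collapse = ", ")))
  invisible(x)
}

#' Region-specific P-spline densities for one component
#'
#' Fits one P-spline density per region to the values of a source row,
#' each on its own padded domain.  With a single region this reduces
#' exactly to the global fit.  The histogram bin count per region
#' follows the same sample-size rule as the global fit, so sparse
#' regions are not over-binned.
#'
#' @param s Numeric source row (length = number of samples).
#' @param map A [parcellation_map()].
#' @param n_basis,degree Spline settings, as in [fit_pspline_density()].
#' @param delta Fixed penalty for every region, or `NULL` to select by
#'   AIC on the pooled (whole-row) histogram once and share the choice
#'   across regions.
#' @param delta_grid Candidates for that selection.
#' @param epsilon_factor Boundary pad multiplier (times the region sd).
#' @return List with `models` (one `"pspline_density"` per region) and
#'   `delta` (the penalty used).
#' @export
fit_region_densities <- function(s, map, n_basis = 25L, degree = 3L,
                                 delta = NULL,
                                 delta_grid = 10^seq(-3, 3, by = 1),
                                 epsilon_factor = 0.1) {
  stopifnot(inherits(map, "parcellation_map"), length(s) == length(map$labels))
  if (is.null(delta)) {
    h_all <- build_histogram(s, epsilon = epsilon_factor * stats::sd(s))
    delta <- select_penalty(h_all, delta_grid, n_basis = n_basis,
                            degree = degree)$delta
  }
  models <- vector("list", map$n_regions)
  for (i in seq_len(map$n_regions)) {
    si <- s[map$labels == i]
    if (length(unique(si)) < 2L)
      stop(sprintf("degenerate region %d: constant values, cannot fit a density", i))
    h <- build_histogram(si, epsilon = epsilon_factor * stats::sd(si))
    models[[i]] <- fit_pspline_density(h, n_basis = n_basis, degree = degree,
                                       delta = delta)
  }
  list(models = models, delta = delta)
}

#' Per-voxel log-density under region-specific models
#'
#' Element `v` is `log f_{r(v)}(s[v])`: every voxel is scored under its
#' own region's density, the voxel-indexed reading of the region-sum
#' density `f(s) = sum_i I(v in R_i) f_i(s)` (exactly one indicator is
#' active per voxel, so each contribution is a proper log-density).
#'
#' @inheritParams fit_region_densities
#' @param models List of fitted region densities (from
#'   [fit_region_densities()]`$models`).
#' @return Numeric vector of log densities, floored as in
#'   [density_eval()].
#' @export
per_voxel_log_density <- function(s, map, models) {
  stopifnot(inherits(map, "parcellation_map"), length(s) == length(map$labels))
  if (length(models) != map$n_regions)
    stop("need one fitted model per region")
  out <- numeric(length(s))
  for (i in seq_len(map$n_regions)) {
    sel <- map$labels == i
    out[sel] <- log(density_eval(models[[i]], s[sel]))
  }
  out
}

per_voxel_score <- function(s, map, models, deriv = 1L) {
  out <- numeric(length(s))
  for (i in seq_len(map$n_regions)) {
    sel <- map$labels == i
    out[sel] <- if (deriv == 1L) score_eval(models[[i]], s[sel])
                else score_prime_eval(models[[i]], s[sel])
  }
  out
}

#' Load a parcellation aligned with a data mask
#'
#' Accepts a 3D NIfTI label volume (path or array) together with the
#' mask used to vectorize the data, or a plain integer vector / one-column
#' text table of per-voxel labels.  Voxel ordering follows the same
#' fastest-first linear scan as [read_nifti_series()], so labels line up
#' with data columns.  Background (zero or negative) labels become the
#' "unassigned" region.
#'
#' @param source Path to a NIfTI volume or a one-column text file, or an
#'   array/vector of labels.
#' @param mask Optional logical/0-1 array; required when `source` is a
#'   volume.  Must match the volume's grid.
#' @param min_region_size Passed to [parcellation_map()].
#' @return A [parcellation_map()].
#' @export
load_parcellation <- function(source, mask = NULL, min_region_size = 50L) {
  if (is.character(source)) {
    stopifnot(length(source) == 1L, file.exists(source))
    if (grepl("\\.nii(\\.gz)?$", source)) {
      source <- as.array(RNifti::readNifti(source))
    } else {
      source <- data.table::fread(source, header = FALSE)[[1L]]
    }
  }
  if (!is.null(dim(source)) && length(dim(source)) >= 2L) {
    if (is.null(mask))
      stop("a label volume needs the data mask to extract in-mask voxels")
    mask <- as.array(mask)
    if (!identical(dim(as.array(source)), dim(mask)))
      stop(sprintf("label volume grid %s does not match mask grid %s",
                   paste(dim(as.array(source)), collapse = "x"),
                   paste(dim(mask), collapse = "x")))
    labels <- as.array(source)[mask > 0]
  } else {
    labels <- as.vector(source)
    if (!is.null(mask)) {
      mask <- as.array(mask)
      if (length(labels) == length(mask)) labels <- labels[mask > 0]
      else if (length(labels) != sum(mask > 0))
        stop("label vector length matches neither the grid nor the mask count")
    }
  }
  parcellation_map(labels, min_region_size = min_region_size)
}
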
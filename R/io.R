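#' Read a masked 4D NIfTI series as a T x V matrix
#'
#' Vectorizes a 4D volume over the in-mask voxels.  Columns follow a
#' fixed linear scan of the mask with the first (x) axis varying
#' fastest — R's native array order — so the same mask always yields the
#' same voxel ordering, and a parcellation volume read through
#' [load_parcellation()] with the same mask lines up column-for-column.
#'
#' @param path_4d Path to a 4D NIfTI volume (or an already-loaded 4D
#'   array / `niftiImage`).
#' @param path_mask Path to a 3D mask on the same grid (or array).
#'   Values > 0 are in-mask; a non-binary mask triggers a warning.
#' @return An object of class `"masked_series"`: `values` (T x V),
#'   `mask` (logical 3D array), `mask_index` (V x 3 integer matrix of
#'   voxel coordinates), and `template` (the mask image, carrying
#'   grid/affine metadata for round-trip writing).
#' @export
read_nifti_series <- function(path_4d, path_mask) {
  img <- if (is.character(path_4d)) RNifti::readNifti(path_4d) else path_4d
  msk <- if (is.character(path_mask)) RNifti::readNifti(path_mask) else path_mask
  arr <- as.array(img)
  mask_arr <- as.array(msk)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L) stop("data volume must be 4D (x, y, z, t)")
  if (!identical(dim(arr)[1:3], dim(mask_arr)))
    stop(sprintf("data grid %s does not match mask grid %s",
                 paste(dim(arr)[1:3], collapse = "x"),
                 paste(dim(mask_arr), collapse = "x")))
  vals <- unique(as.vector(mask_arr))
  if (!all(vals %in% c(0, 1)))
    warning("mask is not binary; treating all values > 0 as in-mask")
  mask <- mask_arr > 0
  if (!any(mask)) stop("mask selects no voxels")
  Tn <- dim(arr)[4L]
  flat <- matrix(arr, ncol = Tn)            # voxels x time, x fastest
  values <- t(flat[as.vector(mask), , drop = FALSE])
  structure(
    list(values = values, mask = mask,
         mask_index = which(mask, arr.ind = TRUE),
         template = msk),
    class = "masked_series")
}

#' @export
print.masked_series <- function(x, ...) {
  cat(sprintf("Masked volume series: T = %d frames, V = %d in-mask voxels (grid %s)\n",
              nrow(x$values), ncol(x$values),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Write spatial maps back into volume space
#'
#' Scatters each row of `S` into the in-mask voxels of the series' grid
#' (background zero) and writes a 4D NIfTI with one frame per component,
#' reusing the series' grid metadata.
#'
#' @param S Q x V matrix of spatial maps; V must match the series mask.
#' @param series A `"masked_series"` (its mask and template are used).
#' @param path Output file path (`.nii` or `.nii.gz`); if `NULL` the 4D
#'   array is returned instead of written.
#' @return The 4D array, invisibly when written to file.
#' @export
write_spatial_maps <- function(S, series, path = NULL) {
  stopifnot(inherits(series, "masked_series"), is.matrix(S))
  V <- sum(series$mask)
  if (ncol(S) != V)
    stop(sprintf("S has %d columns but the mask selects %d voxels", ncol(S), V))
  Q <- nrow(S)
  out <- array(0, dim = c(dim(series$mask), Q))
  flat <- matrix(out, ncol = Q)
  flat[as.vector(series$mask), ] <- t(S)
  out <- array(flat, dim = c(dim(series$mask), Q))
  if (is.null(path)) return(out)
  RNifti::writeNifti(RNifti::asNifti(out, reference = series$template), path)
  invisible(out)
}

#' Headerless delimited matrix exchange
#'
#' Thin wrappers over data.table's reader/writer for the tab-delimited,
#' headerless matrix files the command-line interface exchanges.
#'
#' @param path File path.
#' @param X Numeric matrix.
#' @return `read_matrix()`: a numeric matrix.
#' @export
read_matrix <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE))
}

#' @rdname read_matrix
#' @export
write_matrix <- function(X, path) {
  data.table::fwrite(data.table::as.data.table(X), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Writes a JSON record of a run: inputs, settings, seed, package
#' version, and timestamp.  Every command-line entry point emits one so
#' outputs are traceable.
#'
#' @param path Output JSON path.
#' @param ... Named fields to record.
#' @export
write_manifest <- function(path, ...) {
  rec <- c(list(package = "pspica",
                version = as.character(utils::packageVersion("pspica")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(...))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
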
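#' Construct a validated voxel timeseries matrix
#'
#' Wraps a timepoints-by-voxels signal matrix together with its voxel index
#' lookup. On ingestion every voxel timeseries is z-scored (zero mean, unit
#' SD over time). Pearson-correlation fingerprints are invariant to this
#' per-voxel standardization, and it makes the variance-rescaled and
#' voxelwise fingerprint variants exactly equivalent (all target voxels carry
#' the same temporal norm), mirroring pipelines that z-score timeseries
#' within run before analysis.
#'
#' @param data numeric matrix, `t` timepoints x `v` voxels.
#' @param voxel_ids integer vector of length `v`: linear voxel indices into
#'   the source mask volume (any unique ordered ids for tabular input).
#' @param region_tag `"seed"` or `"target"`.
#' @return An object of class `congradr_timeseries` with elements `data`
#'   (z-scored matrix), `voxel_ids`, `region_tag`.
#' @export
#' @examples
#' ts <- timeseries_matrix(matrix(rnorm(60), 20, 3), 1:3, "seed")
#' dim(ts$data)
timeseries_matrix <- function(data, voxel_ids = seq_len(ncol(data)),
                              region_tag = c("seed", "target")) {
  region_tag <- match.arg(region_tag)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 3L) {
    stop("timeseries must have at least 3 timepoints, got ", nrow(data),
         call. = FALSE)
  }
  if (ncol(data) < 1L) stop("timeseries must have at least 1 voxel", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("timeseries contains non-finite values", call. = FALSE)
  }
  voxel_ids <- as.integer(voxel_ids)
  if (length(voxel_ids) != ncol(data)) {
    stop("voxel_ids length (", length(voxel_ids), ") != voxel count (",
         ncol(data), ")", call. = FALSE)
  }
  if (anyDuplicated(voxel_ids)) stop("voxel_ids must be unique", call. = FALSE)
  data <- zscore_cols(data, what = paste0(region_tag, " timeseries"))
  dimnames(data) <- NULL
  structure(
    list(data = data, voxel_ids = voxel_ids, region_tag = region_tag),
    class = "congradr_timeseries"
  )
}

#' @export
print.congradr_timeseries <- function(x, ...) {
  cat(sprintf("<congradr_timeseries> %s: %d timepoints x %d voxels\n",
              x$region_tag, nrow(x$data), ncol(x$data)))
  invisible(x)
}

n_timepoints <- function(ts) nrow(ts$data)
n_voxels <- function(ts) ncol(ts$data)

as_timeseries <- function(x, region_tag) {
  if (inherits(x, "congradr_timeseries")) return(x)
  timeseries_matrix(x, region_tag = region_tag)
}
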
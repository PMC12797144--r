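# Timeseries extraction from volumes, and TSV interchange.

#' Extract masked voxel timeseries from a 4D image
#'
#' Pulls the timeseries of every voxel whose mask label is in
#' `labels`, ordered by ascending linear voxel index in the mask's native
#' array order (the package-wide voxel ordering convention). Voxels with
#' constant signal are excluded and reported. Millimeter coordinates come
#' from the affine with the center-of-voxel convention on 0-based indices.
#'
#' @param image 4D array, or path to a 4D NIfTI file.
#' @param mask 3D integer array, or path to a NIfTI label volume; grids
#'   must match (and affines agree within tolerance when both are files).
#' @param labels mask labels to select (default: all non-zero).
#' @param region_tag `"seed"` or `"target"`.
#' @param affine 4 x 4 affine when `image` is an array (default identity).
#' @return list with `timeseries` ([timeseries_matrix()], voxel_ids =
#'   linear indices), `geometry` (m x 3 mm), `excluded` (linear indices of
#'   dropped constant voxels).
#' @export
extract_timeseries <- function(image, mask, labels = NULL,
                               region_tag = c("seed", "target"),
                               affine = NULL) {
  region_tag <- match.arg(region_tag)
  if (is.character(image)) {
    img <- read_nifti(image)
    image <- img$data
    affine <- affine %||% img$affine
  }
  mask_affine <- NULL
  if (is.character(mask)) {
    msk <- read_nifti(mask)
    mask_affine <- msk$affine
    mask <- msk$data
  }
  affine <- affine %||% mask_affine %||% diag(4)
  if (!is.null(mask_affine) && max(abs(affine - mask_affine)) > 1e-4) {
    stop("image and mask affines disagree:\nimage:\n",
         paste(apply(affine, 1, paste, collapse = " "), collapse = "\n"),
         "\nmask:\n",
         paste(apply(mask_affine, 1, paste, collapse = " "), collapse = "\n"),
         call. = FALSE)
  }
  image <- as.array(image)
  mask <- as.array(mask)
  if (length(dim(image)) != 4L) stop("image must be 4D", call. = FALSE)
  if (length(dim(mask)) != 3L) stop("mask must be 3D", call. = FALSE)
  if (!all(dim(image)[1:3] == dim(mask))) {
    stop("image grid ", paste(dim(image)[1:3], collapse = "x"),
         " does not match mask grid ", paste(dim(mask), collapse = "x"),
         call. = FALSE)
  }
  sel <- if (is.null(labels)) mask != 0 else {
    present <- unique(as.vector(mask))
    missing_l <- setdiff(labels, present)
    if (length(missing_l)) {
      stop("label(s) absent from mask: ", paste(missing_l, collapse = ", "),
           call. = FALSE)
    }
    array(mask %in% labels, dim = dim(mask))
  }
  idx <- which(sel)                               # ascending linear index
  if (!length(idx)) stop("mask selects no voxels", call. = FALSE)
  nt <- dim(image)[4L]
  flat <- matrix(image, prod(dim(mask)), nt)
  ts <- t(flat[idx, , drop = FALSE])              # t x m
  sds <- apply(ts, 2L, sd)
  excluded <- idx[sds < .Machine$double.eps * 100]
  if (length(excluded)) {
    keep <- !(idx %in% excluded)
    idx <- idx[keep]
    ts <- ts[, keep, drop = FALSE]
    message("excluded ", length(excluded), " constant-signal voxel(s): ",
            paste(head(excluded, 10L), collapse = ", "))
  }
  ijk <- arrayInd(idx, dim(mask)) - 1L            # 0-based
  list(
    timeseries = timeseries_matrix(ts, voxel_ids = idx, region_tag = region_tag),
    geometry = voxel_coordinates(ijk, affine),
    excluded = excluded
  )
}

#' Write / read a timeseries matrix as TSV
#'
#' Timepoints are rows; the header row carries voxel ids (`v<id>`).
#'
#' @param ts [timeseries_matrix()] (write) or file path (read).
#' @param path output path.
#' @param region_tag region tag to attach on read.
#' @return the path (write) or a [timeseries_matrix()] (read).
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "congradr_timeseries"))
  dt <- data.table::as.data.table(ts$data)
  data.table::setnames(dt, paste0("v", ts$voxel_ids))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path, region_tag = c("seed", "target")) {
  region_tag <- match.arg(region_tag)
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.integer(sub("^v", "", names(dt)))
  timeseries_matrix(as.matrix(dt), voxel_ids = ids, region_tag = region_tag)
}

#' Write / read a voxel-keyed matrix as TSV
#'
#' Generic export for similarity matrices, gradients, difference maps:
#' first column `voxel_id`, remaining columns the matrix.
#'
#' @param x numeric matrix (voxels in rows).
#' @param path file path.
#' @param voxel_ids integer ids, one per row.
#' @param col_names optional column names for the matrix part.
#' @return the path (write); list `(data, voxel_ids)` (read).
#' @export
write_voxel_matrix_tsv <- function(x, path, voxel_ids = seq_len(nrow(x)),
                                   col_names = NULL) {
  x <- as.matrix(x)
  cn <- col_names %||% paste0("c", seq_len(ncol(x)))
  dt <- data.table::data.table(voxel_id = as.integer(voxel_ids))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::setnames(dt, c("voxel_id", cn))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_voxel_matrix_tsv
#' @export
read_voxel_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  list(data = as.matrix(dt[, -1L]), voxel_ids = dt[[1L]])
}

#' Write a gradient map into a volume
#'
#' Places per-voxel gradient values at their linear voxel indices inside a
#' volume of the given dimensions (background NA -> 0) and writes NIfTI.
#'
#' @param values numeric vector, one value per voxel id.
#' @param voxel_ids linear indices into the volume.
#' @param dim3 3-vector volume dimensions.
#' @param path output `.nii`/`.nii.gz` path.
#' @param affine 4 x 4 affine.
#' @return the path, invisibly.
#' @export
write_gradient_volume <- function(values, voxel_ids, dim3, path,
                                  affine = diag(4)) {
  vol <- array(0, dim = dim3)
  vol[voxel_ids] <- values
  write_nifti(vol, path, affine = affine, datatype = "float32")
}
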
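#' Scalar image volume
#'
#' A minimal in-memory container for a 3-D scalar image: a numeric array,
#' a 4x4 voxel-to-world affine (RAS, mm) and free-form metadata. Used for
#' probability-of-connection (PICo) sample-count maps, quantitative MT /
#' R2* channels and Jacobian-determinant fields alike.
#'
#' Voxel indices are 0-based throughout the package; world coordinates are
#' obtained as `affine %*% c(i, j, k, 1)`. "Anterior" means increasing
#' world y.
#'
#' @param data 3-D numeric array. All values must be finite.
#' @param affine 4x4 invertible voxel-to-world transform (defaults to
#'   identity, i.e. a 1 mm isotropic grid at the origin).
#' @param meta Named list of free-form metadata.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4), meta = list()) {
  data <- check_volume_data(data)
  check_affine(affine)
  structure(list(data = data, affine = affine, meta = meta),
            class = c("scalar_volume", "stn_volume"))
}

#' Label (integer) image volume
#'
#' Like [scalar_volume()] but for non-negative integer label maps
#' (region-of-interest parcellations, STN masks, cluster labels). Value 0
#' is reserved for background; every nonzero value must be named in
#' `label_names`.
#'
#' @inheritParams scalar_volume
#' @param data 3-D array of non-negative integers.
#' @param label_names Named character vector mapping label id (as name)
#'   to region name, e.g. `c("1" = "thalamus", "2" = "pallidum")`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine = diag(4), label_names = NULL,
                         meta = list()) {
  data <- check_volume_data(data)
  if (any(data < 0) || any(data != round(data)))
    stop("label volume data must be non-negative integers")
  storage.mode(data) <- "integer"
  check_affine(affine)
  present <- setdiff(sort(unique(as.vector(data))), 0L)
  if (is.null(label_names))
    label_names <- stats::setNames(as.character(present), present)
  if (is.null(names(label_names)))
    stop("label_names must be a named vector (names are label ids)")
  missing_ids <- setdiff(present, as.integer(names(label_names)))
  if (length(missing_ids) > 0L)
    stop("label value(s) without a name in label_names: ",
         paste(missing_ids, collapse = ", "))
  structure(list(data = data, affine = affine,
                 label_names = label_names, meta = meta),
            class = c("label_volume", "stn_volume"))
}

check_volume_data <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array (got ",
         paste(dim(data), collapse = "x"), ")")
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data))[1L]
    idx <- arrayInd(bad, dim(data)) - 1L
    stop("non-finite value at voxel index (",
         paste(idx, collapse = ", "), ")")
  }
  data
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine is not invertible")
  invisible(affine)
}

#' @export
print.stn_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "scalar_volume"
  cat(sprintf("<%s> %s voxels\n", kind, paste(dim(x$data), collapse = " x ")))
  if (inherits(x, "label_volume"))
    cat("  labels:", paste(x$label_names, collapse = ", "), "\n")
  else
    cat(sprintf("  range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.stn_volume <- function(x) dim(x$data)

# voxel spacing (mm) along each axis, from the affine column norms
voxel_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# world coordinates (mm) of 0-based voxel indices; ijk is n x 3
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (dim/affine mismatch)")
  invisible(TRUE)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D `.nii` / `.nii.gz` file. If a `<stem>.labels.json` sidecar
#' (written by [write_volume()] for label volumes) sits next to the image
#' and the data are integer-valued, a [label_volume()] is returned;
#' otherwise a [scalar_volume()]. Images containing NaN or infinite voxels
#' are rejected with the offending voxel index.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A `scalar_volume` or `label_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # NIfTI headers drop trailing singleton dimensions; restore them
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(dim(img)), "-D: ", path)
  dim(img) <- d
  affine <- structure(unclass(RNifti::xform(img)), imagedim = NULL,
                      code = NULL)
  data <- array(as.numeric(img), dim = dim(img))
  data <- check_volume_data(data)
  sc <- sidecar_path(path)
  if (file.exists(sc) && all(data == round(data))) {
    labels <- unlist(jsonlite::read_json(sc))
    label_volume(data, affine = affine, label_names = labels)
  } else {
    scalar_volume(data, affine = affine)
  }
}

#' Write a volume to NIfTI-1
#'
#' Label volumes are written as 32-bit integers (bit-exact round trip)
#' together with a `<stem>.labels.json` sidecar holding the label names;
#' scalar volumes as 64-bit floats.
#'
#' @param v A `scalar_volume` or `label_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`. The parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "stn_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  is_label <- inherits(v, "label_volume")
  if (is_label) {
    present <- setdiff(unique(as.vector(v$data)), 0L)
    unnamed <- setdiff(present, as.integer(names(v$label_names)))
    if (length(unnamed) > 0L)
      stop("refusing to write: unnamed label value(s) ",
           paste(unnamed, collapse = ", "))
  }
  dt <- if (is_label) "int32" else "double"
  img <- RNifti::asNifti(v$data, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (is_label)
    jsonlite::write_json(as.list(v$label_names), sidecar_path(path),
                         auto_unbox = TRUE)
  invisible(path)
}
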
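#' Gray-matter density volume
#'
#' A `gm_volume` wraps a 3D array of gray-matter density values (unitless,
#' in \[0, 1\], as produced by tissue segmentation) together with the voxel
#' size and subject/visit identifiers. It is the raw input to network
#' extraction.
#'
#' @param data 3D numeric array of densities in \[0, 1\]; every axis must
#'   have at least 9 voxels (three 3x3x3 cube nodes).
#' @param voxel_size_mm Numeric triple of positive voxel edge lengths (mm).
#' @param subject_id Character scalar.
#' @param visit Visit index, 1 or 2.
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, voxel_size_mm = c(1, 1, 1),
                      subject_id = "synthetic", visit = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 9L)) {
    stop("volume must be at least 9 voxels along every axis", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values", call. = FALSE)
  if (min(data) < 0 || max(data) > 1) {
    stop("density values must lie in [0, 1]", call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive lengths", call. = FALSE)
  }
  visit <- as.integer(visit)
  if (!visit %in% c(1L, 2L)) stop("`visit` must be 1 or 2", call. = FALSE)
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         subject_id = as.character(subject_id), visit = visit),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gm_volume> subject %s, visit %d, %dx%dx%d voxels (%.1fx%.1fx%.1f mm), density range [%.3f, %.3f]\n",
              x$subject_id, x$visit, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer-labeled atlas volume
#'
#' Region labels on the same voxel grid as a paired [gm_volume()]; label 0 is
#' background. Used to aggregate nodal metrics into anatomical regions.
#'
#' @param labels 3D array of non-negative integer region IDs.
#' @param region_names Named character vector mapping label (as name) to
#'   region name; every nonzero label present in `labels` must appear.
#' @return An object of class `gm_atlas`.
#' @export
gm_atlas <- function(labels, region_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative", call. = FALSE)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  if (is.null(region_names)) {
    region_names <- setNames(sprintf("region_%03d", ids), ids)
  }
  missing <- setdiff(as.character(ids), names(region_names))
  if (length(missing)) {
    stop("labels without a region name: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = labels, region_names = region_names),
            class = "gm_atlas")
}

#' @export
print.gm_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<gm_atlas> %dx%dx%d voxels, %d regions\n",
              d[1], d[2], d[3], length(x$region_names)))
  invisible(x)
}

#' Read a gray-matter volume from a NIfTI-1 file
#'
#' @param path Path to a 3D `.nii` or `.nii.gz` file with values in \[0, 1\].
#' @param subject_id,visit Identifiers attached to the returned volume.
#' @return A [gm_volume()].
#' @export
read_volume <- function(path, subject_id = basename(path), visit = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D image, got %d dimensions in %s",
                 length(d), path), call. = FALSE)
  }
  vox <- RNifti::pixdim(img)[seq_len(3L)]
  gm_volume(array(as.numeric(img), dim = d), voxel_size_mm = vox,
            subject_id = subject_id, visit = visit)
}

#' Write a gray-matter volume to a NIfTI-1 file
#'
#' @param vol A [gm_volume()].
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
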
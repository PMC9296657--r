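#' Magnitude MR image volume
#'
#' Lightweight container for a 3-D magnitude image: a non-negative voxel
#' array plus voxel spacing (mm) and a modality tag. Acquisition metadata
#' (TR and friends) is carried as an opaque list and never interpreted.
#'
#' @param data numeric 3-D array of finite, non-negative voxel values.
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param modality one of `"na23"`, `"h1"`, `"dwi"`.
#' @param meta optional named list of pass-through acquisition metadata.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, modality = c("na23", "h1", "dwi"),
                         meta = list()) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_config("data must be a 3-D array")
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0))
    stop_config("voxel values must be finite and non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_config("spacing must be three positive values (mm/voxel)")
  structure(list(data = data, spacing = spacing, modality = modality,
                 meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Named ROI masks on an image grid
#'
#' Binds named binary masks (tumour / non-tumour / phantom, or any other
#' role) to the voxel grid of one [image_volume()]. Masks must be non-empty
#' and share the image's shape.
#'
#' @param masks named list of logical arrays.
#' @param image the `image_volume` the masks refer to (shape check only).
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks, image = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop_config("masks must be a named list of logical arrays")
  ref_dim <- if (!is.null(image)) dim(image$data) else dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), ref_dim))
      stop_config("mask '", nm, "' must be logical with the image's shape")
    if (!any(m)) stop_config("mask '", nm, "' is empty")
  }
  structure(list(masks = masks, grid_shape = ref_dim), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  n <- vapply(x$masks, sum, integer(1))
  cat("<roi_set>", paste(sprintf("%s(%d vox)", names(n), n), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write image volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. `write_image_volume()` stores the voxel
#' array with its spacing in the NIfTI header and an optional JSON sidecar
#' carrying modality and free-form metadata; `read_image_volume()` restores
#' the `image_volume`, consulting the sidecar when present.
#'
#' @param image an [image_volume()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param sidecar write/read a `.json` sidecar next to `path`?
#' @return `read_image_volume()` returns an `image_volume`;
#'   `write_image_volume()` returns `path` invisibly.
#' @export
write_image_volume <- function(image, path, sidecar = TRUE) {
  nif <- RNifti::asNifti(image$data)
  RNifti::pixdim(nif) <- image$spacing
  RNifti::writeNifti(nif, path)
  if (sidecar) {
    jp <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(c(list(modality = image$modality), image$meta),
                         jp, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_image_volume
#' @param modality fallback modality when no sidecar is found.
#' @export
read_image_volume <- function(path, modality = "na23", sidecar = TRUE) {
  nif <- RNifti::readNifti(path)
  meta <- list()
  jp <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (sidecar && file.exists(jp)) {
    meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
    modality <- meta$modality %||% modality
    meta$modality <- NULL
  }
  arr <- as.array(nif)
  arr <- array(as.numeric(arr), dim = dim(arr))  # drop NIfTI attributes
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_volume(arr, RNifti::pixdim(nif)[1:3], modality, meta)
}

#' Write an ROI set as an integer-labelled NIfTI mask
#'
#' Labels follow the convention 1 = tumour, 2 = non_tumour, 3 = phantom;
#' any further ROIs get consecutive labels in list order. Overlapping masks
#' are rejected since one voxel can hold only one label.
#'
#' @param rois an [roi_set()].
#' @param path output path; spacing of `image` is stored in the header.
#' @param image the parent `image_volume` (for spacing).
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path, image) {
  canonical <- c(tumour = 1L, non_tumour = 2L, phantom = 3L)
  labels <- integer(length(rois$masks))
  names(labels) <- names(rois$masks)
  labels[names(labels) %in% names(canonical)] <-
    canonical[names(labels)[names(labels) %in% names(canonical)]]
  labels[labels == 0L] <- max(labels, 3L) + seq_len(sum(labels == 0L))
  lab <- array(0L, dim = rois$grid_shape)
  for (nm in names(rois$masks)) {
    if (any(lab[rois$masks[[nm]]] != 0L))
      stop_config("masks overlap; cannot write a single label volume")
    lab[rois$masks[[nm]]] <- labels[nm]
  }
  nif <- RNifti::asNifti(lab)
  RNifti::pixdim(nif) <- image$spacing
  RNifti::writeNifti(nif, path)
  invisible(path)
}
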
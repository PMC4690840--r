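#' Tagged 3D label image
#'
#' Container for an anatomically tagged segmentation: a 3D grid of integer
#' voxel labels (0 = background) with physical-space metadata and a tag table
#' naming each label. The voxel-to-world mapping is axis-aligned:
#' the center of 0-based voxel \code{(i,j,k)} sits at
#' \code{origin + (i + 0.5) * spacing}.
#'
#' @param voxels 3D integer array of labels; 0 is background.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world coordinate (mm) of the lower corner
#'   of voxel (0,0,0).
#' @param tags named character vector mapping labels to region names, e.g.
#'   \code{c("1" = "LV_myo", "2" = "RV_myo")}. Every nonzero label present in
#'   \code{voxels} must appear; missing entries are auto-named
#'   \code{"tag_<label>"}.
#' @return an object of class \code{label_image}.
#' @export
label_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        tags = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (is.double(voxels)) {
    if (max(abs(voxels - round(voxels)), 0) > 1e-9)
      stop("non-integer labels in voxel data")
  }
  # normalize to a plain integer array (drop any foreign classes/attributes)
  voxels <- array(as.integer(round(as.vector(voxels))), dim = dim(voxels))
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive in all axes")
  labs <- sort(unique(as.vector(voxels)))
  labs <- labs[labs != 0L]
  if (any(labs < 0L) || any(labs > 65535L))
    stop("labels must lie in 0..65535")
  if (is.null(tags)) tags <- character(0)
  tags <- stats::setNames(as.character(tags), names(tags))
  missing <- setdiff(as.character(labs), names(tags))
  if (length(missing))
    tags[missing] <- paste0("tag_", missing)
  tags <- tags[order(as.integer(names(tags)))]
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 tags = tags),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_image: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin: (%g, %g, %g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  tab <- table(factor(x$voxels[x$voxels != 0L],
                      levels = as.integer(names(x$tags))))
  for (l in names(x$tags))
    cat(sprintf("  label %s (%s): %d voxels\n", l, x$tags[[l]],
                as.integer(tab[l])))
  invisible(x)
}

#' @export
dim.label_image <- function(x) dim(x$voxels)

# World coordinates of voxel centers along one axis (1-based R index).
voxel_centers <- function(image, axis) {
  n <- dim(image$voxels)[axis]
  image$origin[axis] + (seq_len(n) - 0.5) * image$spacing[axis]
}

# World-space bounds of the image (outer voxel faces).
image_bounds <- function(image) {
  d <- dim(image$voxels)
  list(lower = image$origin, upper = image$origin + d * image$spacing)
}

#' Look up the integer label for a named region
#' @param image a \code{label_image}.
#' @param name region name as stored in the tag table.
#' @return integer label.
#' @export
tag_label <- function(image, name) {
  hit <- names(image$tags)[image$tags == name]
  if (!length(hit)) stop(sprintf("no tag named '%s' in tag table", name))
  as.integer(hit[1])
}

#' Binary mask of a set of tags
#'
#' Returns a \code{label_image} whose voxels are 1 where the input label is in
#' \code{tags} and 0 elsewhere; geometry metadata is unchanged.
#'
#' @param image a \code{label_image}.
#' @param tags integer labels or region names; may be empty.
#' @return a \code{label_image} with values in \{0, 1\}.
#' @export
binary_mask <- function(image, tags) {
  tags <- resolve_tags(image, tags)
  mask <- array(0L, dim = dim(image$voxels))
  if (length(tags))
    mask[image$voxels %in% tags] <- 1L
  label_image(mask, image$spacing, image$origin, c("1" = "mask"))
}

# Map a vector of labels or region names to integer labels, validating
# against the tag table.
resolve_tags <- function(image, tags) {
  if (length(tags) == 0L) return(integer(0))
  if (is.character(tags)) tags <- vapply(tags, tag_label, 1L, image = image)
  tags <- as.integer(tags)
  known <- as.integer(names(image$tags))
  bad <- setdiff(tags, c(known, 0L))
  if (length(bad))
    stop(sprintf("unknown tag(s) requested: %s", paste(bad, collapse = ", ")))
  tags
}

#' Read a tagged label image
#'
#' Reads NIfTI-1 (\code{.nii}, \code{.nii.gz}) or NRRD (\code{.nrrd}) label
#' images. Voxel data must be integer-valued; oblique orientation matrices are
#' rejected (only axis-aligned grids are supported). A tag-table sidecar
#' \code{<path>.tags.json} is read when present.
#'
#' @param path file path.
#' @return a \code{label_image}.
#' @export
read_label_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    img <- read_nrrd_image(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- read_nifti_image(path)
  } else stop("unsupported image format (expect .nii, .nii.gz or .nrrd)")
  sidecar <- paste0(path, ".tags.json")
  if (file.exists(sidecar)) {
    tt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img$tags <- stats::setNames(as.character(tt$labels),
                                names(tt$labels))
    img <- label_image(img$voxels, img$spacing, img$origin, img$tags)
  }
  img
}

#' Write a tagged label image
#'
#' Writes NIfTI-1 or NRRD depending on the file extension, plus a tag-table
#' sidecar \code{<path>.tags.json} (neither format standardizes label names).
#' Round-trips exactly through \code{\link{read_label_image}}.
#'
#' @param image a \code{label_image}.
#' @param path output path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}.
#' @param encoding NRRD payload encoding, \code{"raw"} (default) or
#'   \code{"ascii"}; ignored for NIfTI.
#' @return \code{path}, invisibly.
#' @export
write_label_image <- function(image, path, encoding = "raw") {
  stopifnot(inherits(image, "label_image"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_image(image, path, encoding = encoding)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_image(image, path)
  } else stop("unsupported image format (expect .nii, .nii.gz or .nrrd)")
  jsonlite::write_json(list(labels = as.list(image$tags)),
                       paste0(path, ".tags.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_nifti_image <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  if (is.double(arr) && max(abs(arr - round(arr)), 0) > 1e-6)
    stop("non-integer labels in voxel data")
  xf <- RNifti::xform(nii)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(rot))))
    stop("non-axis-aligned orientation matrix: unsupported geometry")
  if (any(diag(rot) < 0))
    stop("negative-direction orientation matrix: unsupported geometry")
  spacing <- abs(diag(rot))
  if (all(spacing == 0)) spacing <- RNifti::pixdim(nii)[1:3]
  # NIfTI offset is the center of voxel (0,0,0); our origin is its lower corner
  origin <- xf[1:3, 4] - 0.5 * spacing
  label_image(arr, spacing = spacing, origin = origin)
}

write_nifti_image <- function(image, path) {
  arr <- image$voxels
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- image$spacing
  aff <- diag(c(image$spacing, 1))
  aff[1:3, 4] <- image$origin + 0.5 * image$spacing
  RNifti::`sform<-`(nii, structure(aff, code = 2L)) -> nii
  RNifti::`qform<-`(nii, structure(aff, code = 2L)) -> nii
  RNifti::writeNifti(nii, path)
  invisible(path)
}
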
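#' Phantom specification with labelled reward ROIs
#'
#' Describes a digital phantom: a voxel grid carrying disjoint labelled
#' regions named after the reward / cognitive-reward-control areas of the
#' analysis mask (NAcc, mOFC, dlPFC, vlPFC, SMA, VTA, basolateral amygdala).
#' ROI voxel sets use 0-based index triples.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param rois Named list; each element an n x 3 integer matrix of 0-based
#'   voxel index triples.
#' @return A list of class `phantom_spec`.
#' @seealso [cuboid_roi()], [default_phantom_spec()]
#' @export
phantom_spec <- function(grid_shape, rois) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            is.list(rois), length(rois) >= 1L, !is.null(names(rois)))
  rois <- lapply(rois, function(m) {
    m <- matrix(as.integer(m), ncol = 3L)
    if (any(m < 0L) || any(sweep(m, 2L, grid_shape, ">=")))
      stop("ROI voxel indices outside grid bounds")
    m
  })
  structure(list(grid_shape = grid_shape, rois = rois), class = "phantom_spec")
}

#' Cuboid ROI helper
#'
#' @param origin 0-based corner (3 integers).
#' @param dim Extent in voxels along each axis (3 positive integers).
#' @return An n x 3 integer matrix of 0-based voxel triples.
#' @export
cuboid_roi <- function(origin, dim) {
  origin <- as.integer(origin); dim <- as.integer(dim)
  stopifnot(length(origin) == 3L, length(dim) == 3L, all(dim >= 1L))
  g <- expand.grid(x = origin[1] + seq_len(dim[1]) - 1L,
                   y = origin[2] + seq_len(dim[2]) - 1L,
                   z = origin[3] + seq_len(dim[3]) - 1L)
  as.matrix(g)
}

#' Default reward-mask phantom
#'
#' A compact grid holding all seven labelled regions of the reward analysis
#' mask as disjoint cuboids. Sizes are loosely proportional to the anatomical
#' regions (mOFC and dlPFC largest; VTA smallest).
#'
#' @param grid_shape Grid size, default `c(24, 24, 24)`.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(grid_shape = c(24L, 24L, 24L)) {
  s <- pmax(1L, as.integer(round(grid_shape / 24)))  # scale factor vs reference grid
  sc <- function(v) as.integer(round(v * grid_shape / 24))
  phantom_spec(grid_shape, list(
    NAcc = cuboid_roi(sc(c(4, 4, 4)), pmax(2L, sc(c(3, 3, 3)))),
    VTA = cuboid_roi(sc(c(11, 4, 4)), pmax(1L, sc(c(2, 2, 2)))),
    basolateral_amygdala = cuboid_roi(sc(c(16, 4, 4)), pmax(2L, sc(c(3, 3, 3)))),
    mOFC = cuboid_roi(sc(c(4, 11, 4)), pmax(2L, sc(c(5, 4, 3)))),
    SMA = cuboid_roi(sc(c(13, 11, 4)), pmax(2L, sc(c(4, 3, 3)))),
    dlPFC = cuboid_roi(sc(c(4, 4, 14)), pmax(2L, sc(c(6, 5, 4)))),
    vlPFC = cuboid_roi(sc(c(14, 4, 14)), pmax(2L, sc(c(4, 3, 3))))
  ))
}

#' Build a labelled phantom volume
#'
#' Rasterises a [phantom_spec()] into an integer label volume plus a legend
#' mapping each region name to its label; overlapping ROI definitions are an
#' error.
#'
#' @param spec A `phantom_spec`.
#' @return A list of class `phantom` with `labels` (3D integer array; 0 =
#'   background), `legend` (tibble `label`, `roi`, `n_voxels`) and
#'   `grid_shape`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- array(0L, dim = spec$grid_shape)
  legend <- tibble::tibble(label = seq_along(spec$rois), roi = names(spec$rois),
                           n_voxels = vapply(spec$rois, nrow, integer(1)))
  for (k in seq_along(spec$rois)) {
    idx <- spec$rois[[k]] + 1L
    lin <- idx[, 1] + spec$grid_shape[1] * (idx[, 2] - 1L) +
      spec$grid_shape[1] * spec$grid_shape[2] * (idx[, 3] - 1L)
    if (any(labels[lin] != 0L)) {
      hit <- legend$roi[labels[lin][labels[lin] != 0L][1]]
      stop(sprintf("overlapping ROI definitions: '%s' intersects '%s'",
                   names(spec$rois)[k], hit))
    }
    labels[lin] <- k
  }
  structure(list(labels = labels, legend = legend, grid_shape = spec$grid_shape),
            class = "phantom")
}

#' Union mask of all labelled regions
#'
#' @param phantom A `phantom`.
#' @param roi Optional character vector of region names to restrict to.
#' @return A logical 3D array.
#' @export
union_mask <- function(phantom, roi = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.null(roi)) return(phantom$labels != 0L)
  keep <- phantom$legend$label[phantom$legend$roi %in% roi]
  if (length(keep) == 0L) stop("no matching ROI names")
  array(phantom$labels %in% keep, dim = phantom$grid_shape)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> grid %s, %d ROIs, %d labelled voxels\n",
              paste(x$grid_shape, collapse = "x"), nrow(x$legend),
              sum(x$labels != 0L)))
  print(x$legend)
  invisible(x)
}

#' Write / read NIfTI volumes
#'
#' Thin wrappers over RNifti for the package's image products (4D runs,
#' label masks, searchlight maps).
#'
#' @param x A numeric/integer array (3D or 4D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr Repetition time in seconds, stamped into the header pixdim for
#'   4D images.
#' @return `write_nifti()` returns `path` invisibly; `read_nifti()` returns
#'   a plain array.
#' @export
write_nifti <- function(x, path, tr = NULL) {
  img <- RNifti::asNifti(x)
  if (!is.null(tr) && length(dim(x)) == 4L) {
    RNifti::pixdim(img) <- c(1, 1, 1, tr)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

# 0-based voxel coords (n x 3) of TRUE entries of a 3D logical mask,
# in the linear (column-major) order used throughout the package.
mask_coords <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  w <- which(mask)
  arr <- arrayInd(w, dim(mask)) - 1L
  colnames(arr) <- c("x", "y", "z")
  arr
}
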
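#' Image volumes and binary masks
#'
#' `image_volume()` wraps a 3-D numeric array of CT-like (Hounsfield-unit)
#' intensities together with its voxel spacing and world origin.
#' `binary_mask()` does the same for a logical segmentation mask.  The array
#' is indexed `[x, y, z]` (first index fastest); the world position of voxel
#' `(i, j, k)` center is `origin + (i-1, j-1, k-1) * spacing`, in mm.
#'
#' @param data 3-D numeric (volume) or logical (mask) array, at least 2
#'   voxels per axis, all values finite.
#' @param spacing numeric length-3, mm per voxel along x, y, z; all > 0.
#' @param origin numeric length-3, world-mm position of the center of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `segqa_volume` or `segqa_mask`: a list with
#'   elements `data`, `spacing`, `origin`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' m <- binary_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 2))
#' mask_volume_mm3(m)  # 64 voxels x 2 mm^3
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  check_grid_args(data, spacing, origin)
  if (!is.numeric(data))
    stop("volume data must be numeric")
  if (!all(is.finite(data)))
    stop("volume data must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "segqa_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  check_grid_args(data, spacing, origin)
  if (!is.logical(data))
    storage.mode(data) <- "logical"
  if (anyNA(data))
    stop("mask data must not contain NA")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "segqa_mask")
}

check_grid_args <- function(data, spacing, origin) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("data must have at least 2 voxels per axis")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  invisible(TRUE)
}

#' @export
print.segqa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segqa_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.segqa_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<segqa_mask> %d x %d x %d voxels, spacing (%g, %g, %g) mm, %d true (%.2f mm^3)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$data), mask_volume_mm3(x)))
  invisible(x)
}

#' @export
plot.segqa_volume <- function(x, z = NULL, ...) {
  if (is.null(z)) z <- ceiling(dim(x$data)[3] / 2)
  image(axis_coords(x, 1), axis_coords(x, 2), x$data[, , z],
        col = gray(seq(0, 1, length.out = 128)), asp = 1,
        xlab = "x (mm)", ylab = "y (mm)",
        main = sprintf("slice z = %d", z), ...)
  invisible(x)
}

#' Grid helpers
#'
#' `mask_volume_mm3()` is the voxel-count volume of a mask;
#' `voxel_volume_mm3()` the volume of one voxel; `axis_coords()` the world
#' coordinates of voxel centers along one axis; `same_grid()` tests whether
#' two volumes/masks share dimensions, spacing and origin.
#'
#' @param x,a,b volumes or masks.
#' @param axis axis index 1 (x), 2 (y) or 3 (z).
#' @param tol comparison tolerance for spacing/origin, in mm.
#' @return `mask_volume_mm3`/`voxel_volume_mm3`: a number (mm^3);
#'   `axis_coords`: a numeric vector; `same_grid`: TRUE/FALSE.
#' @export
mask_volume_mm3 <- function(x) {
  sum(x$data) * voxel_volume_mm3(x)
}

#' @rdname mask_volume_mm3
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' @rdname mask_volume_mm3
#' @export
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis]
}

#' @rdname mask_volume_mm3
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# world coordinates of every voxel center, as three arrays (memoised callers
# should prefer axis_coords + outer sums where the predicate is separable)
world_grid <- function(x) {
  d <- dim(x$data)
  list(
    x = array(rep(axis_coords(x, 1), times = d[2] * d[3]), d),
    y = array(rep(rep(axis_coords(x, 2), each = d[1]), times = d[3]), d),
    z = array(rep(axis_coords(x, 3), each = d[1] * d[2]), d)
  )
}
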
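#' Global intensity thresholding
#'
#' Marks every voxel whose intensity lies in `[hu_min, hu_max]` (inclusive on
#' both ends) — the principal starting point of bone segmentation workflows.
#'
#' @param volume an [image_volume()].
#' @param hu_min,hu_max intensity bounds, HU; `hu_min <= hu_max`.
#' @return A [binary_mask()] on the volume's grid.
#' @export
threshold_mask <- function(volume, hu_min, hu_max) {
  stopifnot(inherits(volume, "segqa_volume"))
  if (hu_min > hu_max)
    stop("hu_min must be <= hu_max (got ", hu_min, " > ", hu_max, ")")
  binary_mask(volume$data >= hu_min & volume$data <= hu_max,
              volume$spacing, volume$origin)
}

#' Seeded region growing
#'
#' Thresholds the volume, then keeps only the connected components (of the
#' stated voxel connectivity) that contain at least one seed.  The result is
#' always a subset of the plain threshold mask.
#'
#' @param volume an [image_volume()].
#' @param seeds matrix (or vector) of 1-based voxel indices, one seed per
#'   row, columns (i, j, k).
#' @param hu_min,hu_max intensity bounds as in [threshold_mask()].
#' @param connectivity 6, 18 or 26.
#' @return A [binary_mask()].  Seeds whose intensity falls outside the range
#'   are dropped with a warning; if no seed is valid the mask is empty and a
#'   warning is raised (a likely user error).
#' @export
region_grow <- function(volume, seeds, hu_min, hu_max, connectivity = 26) {
  stopifnot(inherits(volume, "segqa_volume"))
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(volume$data)
  if (any(seeds < 1) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed indices outside the volume grid")
  thr <- threshold_mask(volume, hu_min, hu_max)
  valid <- thr$data[seeds]
  if (!all(valid))
    warning(sum(!valid), " seed(s) fall outside the intensity range and were dropped")
  if (!any(valid)) {
    warning("no valid seed: region growing returns an empty mask")
    return(binary_mask(array(FALSE, d), volume$spacing, volume$origin))
  }
  lab <- array(.cc_label_cpp(as.vector(thr$data), d, as.integer(connectivity)), d)
  keep <- unique(lab[seeds[valid, , drop = FALSE]])
  keep <- keep[keep > 0]
  binary_mask(array(lab %in% keep, d), volume$spacing, volume$origin)
}

# Euclidean ball structuring element, radius in voxels
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off[rowSums(off^2) <= radius^2, , drop = FALSE]
}

morph_apply <- function(data, op, radius) {
  d <- dim(data)
  off <- ball_offsets(radius)
  res <- switch(op,
    dilate = .dilate_cpp(as.vector(data), d, off),
    erode = .erode_cpp(as.vector(data), d, off),
    stop("unknown morphology primitive: ", op))
  array(res, d)
}

#' Mask editing by mathematical morphology
#'
#' Applies an ordered list of mask-editing steps.  Each step is either a
#' plain string (`"keep_largest"`, `"fill_holes"`) or a list
#' `list(op =, radius =)` for `"erode"`, `"dilate"`, `"open"`, `"close"`
#' with the radius in voxels (Euclidean ball structuring element).
#' `keep_largest` retains the single largest 26-connected component, ties
#' broken in favor of the component whose first voxel comes first in
#' (z, y, x) raster order; `fill_holes` fills background cavities that do
#' not touch the grid border (6-connected background).
#'
#' @param mask a [binary_mask()].
#' @param steps ordered list of steps; an empty list is the identity.
#' @return A [binary_mask()].
#' @examples
#' g <- grid_spec(c(20, 20, 20), c(1, 1, 1))
#' m <- make_primitive("ball", g, center = c(9, 9, 9), radius = 5)
#' apply_morphology(m, list(list(op = "close", radius = 1), "keep_largest"))
#' @export
apply_morphology <- function(mask, steps = list()) {
  stopifnot(inherits(mask, "segqa_mask"))
  data <- mask$data
  d <- dim(data)
  for (s in steps) {
    if (is.character(s)) s <- list(op = s)
    op <- s$op
    radius <- s$radius %||% 1
    if (!is.character(op) ||
        !op %in% c("erode", "dilate", "open", "close", "keep_largest",
                   "fill_holes"))
      stop("unknown morphology step: ", deparse(op))
    if (op %in% c("erode", "dilate", "open", "close") && radius < 1)
      stop("morphology radius must be >= 1 voxel")
    data <- switch(op,
      erode = morph_apply(data, "erode", radius),
      dilate = morph_apply(data, "dilate", radius),
      open = morph_apply(morph_apply(data, "erode", radius), "dilate", radius),
      close = morph_apply(morph_apply(data, "dilate", radius), "erode", radius),
      keep_largest = {
        lab <- array(.cc_label_cpp(as.vector(data), d, 26L), d)
        if (max(lab) == 0) data
        else {
          counts <- tabulate(lab[lab > 0])
          data & lab == which.max(counts)  # which.max keeps the first (lowest label) on ties
        }
      },
      fill_holes = {
        bg <- array(.cc_label_cpp(as.vector(!data), d, 6L), d)
        border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                           bg[, , 1], bg[, , d[3]]))
        border <- border[border > 0]
        data | (bg > 0 & !(bg %in% border))
      })
  }
  binary_mask(data, mask$spacing, mask$origin)
}

#' Shape-based interpolation between annotated slices
#'
#' Reconstructs a full mask from annotations on a subset of z-slices, the
#' way nerve canals are painted slice-by-slice and interpolated.  For each
#' gap the signed in-plane Euclidean distance fields of the two neighboring
#' annotated slices (positive inside, negative outside) are linearly
#' interpolated and thresholded at zero.  Annotated slices pass through
#' unchanged; slices outside the annotated range stay empty.
#'
#' @param sparse a [binary_mask()] whose annotated z-slices carry the
#'   painted shapes.
#' @param annotated_z integer vector of annotated slice indices (>= 2
#'   slices, each non-empty).
#' @return A [binary_mask()].
#' @export
interpolate_slices <- function(sparse, annotated_z) {
  stopifnot(inherits(sparse, "segqa_mask"))
  annotated_z <- sort(unique(as.integer(annotated_z)))
  d <- dim(sparse$data)
  if (length(annotated_z) < 2)
    stop("need at least 2 annotated slices")
  if (any(annotated_z < 1 | annotated_z > d[3]))
    stop("annotated_z outside the grid")
  for (z in annotated_z)
    if (!any(sparse$data[, , z]))
      stop("annotated slice ", z, " is empty")
  if (abs(sparse$spacing[1] - sparse$spacing[2]) > 1e-9)
    warning("in-plane spacing is anisotropic; distance fields use pixel units")
  sdf <- function(z) {
    fg <- sparse$data[, , z]
    din <- sqrt(array(.edt2d_cpp(as.vector(!fg), d[1], d[2]), d[1:2]))
    dout <- sqrt(array(.edt2d_cpp(as.vector(fg), d[1], d[2]), d[1:2]))
    ifelse(fg, din, -dout)
  }
  out <- array(FALSE, d)
  for (z in annotated_z) out[, , z] <- sparse$data[, , z]
  for (i in seq_len(length(annotated_z) - 1)) {
    z1 <- annotated_z[i]; z2 <- annotated_z[i + 1]
    if (z2 - z1 < 2) next
    f1 <- sdf(z1); f2 <- sdf(z2)
    for (z in (z1 + 1):(z2 - 1)) {
      w <- (z - z1) / (z2 - z1)
      out[, , z] <- (1 - w) * f1 + w * f2 > 0
    }
  }
  binary_mask(out, sparse$spacing, sparse$origin)
}

#' Mask subtraction
#'
#' `a AND NOT b`, the mask-splitting primitive used to separate the tumor
#' from the mandible.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return A [binary_mask()].
#' @export
mask_subtract <- function(a, b) {
  stopifnot(inherits(a, "segqa_mask"), inherits(b, "segqa_mask"))
  if (!same_grid(a, b))
    stop("masks are on different grids")
  binary_mask(a$data & !b$data, a$spacing, a$origin)
}

#' Workflow profiles
#'
#' A named bundle of segmentation and refinement parameters standing in for
#' one software workflow: the threshold window, optional region growing,
#' mask-editing steps, the smoothing algorithm with per-level iteration
#' counts (level 0 = none, 1 = low, 2 = high), and optional decimation.
#'
#' @param name profile label.
#' @param hu_min,hu_max bone threshold window, HU.
#' @param region_grow list `list(enabled =, connectivity =)`; seeds are
#'   provided at run time.
#' @param morphology ordered step list as in [apply_morphology()].
#' @param smoothing list with `algorithm` (`"laplacian"`, `"taubin"` or
#'   `"none"`), `iterations` (length-3 integer vector for levels 0/1/2, the
#'   first entry must be 0), `lambda` and (Taubin) `mu`.
#' @param decimation optional face-count fraction in (0, 1] applied after
#'   smoothing at levels 1-2.
#' @param tumor_window tumor threshold window, HU.
#' @param nerve_stride paint-every-k-th-slice stride of the manual nerve
#'   workflow.
#' @return A list of class `segqa_profile`.
#' @export
workflow_profile <- function(name, hu_min, hu_max = 3000,
                             region_grow = list(enabled = FALSE,
                                                connectivity = 26),
                             morphology = list("keep_largest", "fill_holes"),
                             smoothing = list(algorithm = "taubin",
                                              iterations = c(0, 10, 50),
                                              lambda = 0.33, mu = -0.34),
                             decimation = NULL,
                             tumor_window = c(50, 180),
                             nerve_stride = 2L) {
  if (hu_min > hu_max) stop("hu_min must be <= hu_max")
  if (length(smoothing$iterations) != 3 || smoothing$iterations[1] != 0)
    stop("smoothing$iterations must give levels 0/1/2 and level 0 must be 0")
  if (is.unsorted(smoothing$iterations))
    stop("smoothing levels must be ordered by increasing intensity")
  structure(list(name = name, hu_min = hu_min, hu_max = hu_max,
                 region_grow = region_grow, morphology = morphology,
                 smoothing = smoothing, decimation = decimation,
                 tumor_window = tumor_window,
                 nerve_stride = as.integer(nerve_stride)),
            class = "segqa_profile")
}

#' @rdname workflow_profile
#' @details `default_profiles()` returns four presets that differ in
#'   threshold window, smoothing algorithm and intensity, emulating the
#'   spread of choices across segmentation programs.
#' @export
default_profiles <- function() {
  list(
    workflow_profile("p1", hu_min = 400,
                     smoothing = list(algorithm = "taubin",
                                      iterations = c(0, 10, 50),
                                      lambda = 0.33, mu = -0.34),
                     nerve_stride = 2L),
    workflow_profile("p2", hu_min = 650,
                     smoothing = list(algorithm = "laplacian",
                                      iterations = c(0, 5, 15),
                                      lambda = 0.5),
                     nerve_stride = 3L),
    workflow_profile("p3", hu_min = 500,
                     morphology = list(list(op = "close", radius = 1),
                                       "keep_largest", "fill_holes"),
                     smoothing = list(algorithm = "taubin",
                                      iterations = c(0, 20, 100),
                                      lambda = 0.5, mu = -0.53),
                     nerve_stride = 2L),
    workflow_profile("p4", hu_min = 750,
                     smoothing = list(algorithm = "laplacian",
                                      iterations = c(0, 3, 10),
                                      lambda = 0.3),
                     decimation = 0.8,
                     nerve_stride = 4L)
  )
}
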
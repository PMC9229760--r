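#' Regular grid specification
#'
#' Describes the voxel lattice a phantom is generated on: array dimensions,
#' spacing in mm and the world position of the first voxel center.
#'
#' @param dim integer length-3 array dimensions (x, y, z).
#' @param spacing numeric length-3 voxel spacing, mm.
#' @param origin numeric length-3 world-mm center of voxel (1, 1, 1).
#' @return A list of class `segqa_grid`.
#' @export
grid_spec <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 2L))
    stop("dim must be 3 integers >= 2")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "segqa_grid")
}

grid_extent <- function(grid) {
  # outer bounds of the voxel lattice (voxels own a half-spacing margin)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dim - 1 + 0.5) * grid$spacing
  rbind(lo = lo, hi = hi)
}

check_inside_extent <- function(bbox, grid, what) {
  ext <- grid_extent(grid)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    if (bbox[1, i] < ext["lo", i] || bbox[2, i] > ext["hi", i])
      stop(sprintf(
        "%s spans [%.3f, %.3f] mm along %s, outside the grid extent [%.3f, %.3f]",
        what, bbox[1, i], bbox[2, i], ax[i], ext["lo", i], ext["hi", i]))
  }
  invisible(TRUE)
}

#' Analytic primitive masks
#'
#' Rasterizes an analytic solid onto a voxel grid: a voxel is true iff its
#' center lies inside the shape.  Used as oracle fixtures for the
#' segmentation and meshing stages.
#'
#' @param kind `"ball"`, `"box"` or `"tube"` (a capsule: cylinder with
#'   spherical caps).
#' @param grid a [grid_spec()].
#' @param center,radius ball: center (mm) and radius (mm). Also the tube
#'   radius.
#' @param lo,hi box: opposite corners in mm (closed interval per axis).
#' @param p0,p1 tube: capsule axis endpoints in mm.
#' @return A [binary_mask()] on the grid.
#' @examples
#' g <- grid_spec(c(25, 25, 25), c(1, 1, 1), origin = c(-12, -12, -12))
#' m <- make_primitive("ball", g, center = c(0, 0, 0), radius = 10)
#' mask_volume_mm3(m)  # close to 4/3 pi 10^3
#' @export
make_primitive <- function(kind = c("ball", "box", "tube"), grid,
                           center = NULL, radius = NULL,
                           lo = NULL, hi = NULL, p0 = NULL, p1 = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "segqa_grid"))
  xs <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3]
  data <- switch(kind,
    ball = {
      if (is.null(center) || is.null(radius))
        stop("ball needs center and radius")
      check_inside_extent(rbind(center - radius, center + radius), grid, "ball")
      d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                  (zs - center[3])^2, "+")
      d2 <= radius^2
    },
    box = {
      if (is.null(lo) || is.null(hi)) stop("box needs lo and hi")
      check_inside_extent(rbind(lo, hi), grid, "box")
      inx <- xs >= lo[1] & xs <= hi[1]
      iny <- ys >= lo[2] & ys <= hi[2]
      inz <- zs >= lo[3] & zs <= hi[3]
      outer(outer(inx, iny, "&"), inz, "&")
    },
    tube = {
      if (is.null(p0) || is.null(p1) || is.null(radius))
        stop("tube needs p0, p1 and radius")
      check_inside_extent(rbind(pmin(p0, p1) - radius, pmax(p0, p1) + radius),
                          grid, "tube")
      g <- world_grid(list(data = array(0, grid$dim), spacing = grid$spacing,
                           origin = grid$origin))
      v <- p1 - p0
      vv <- sum(v^2)
      t <- if (vv == 0) 0 else
        pmin(pmax(((g$x - p0[1]) * v[1] + (g$y - p0[2]) * v[2] +
                     (g$z - p0[3]) * v[3]) / vv, 0), 1)
      d2 <- (g$x - p0[1] - t * v[1])^2 + (g$y - p0[2] - t * v[2])^2 +
        (g$z - p0[3] - t * v[3])^2
      array(d2 <= radius^2, grid$dim)
    })
  binary_mask(array(data, grid$dim), grid$spacing, grid$origin)
}

#' Parameters of the mandible/tumor/nerve phantom
#'
#' Defaults emulate the challenge features of a cranio-maxillofacial tumor
#' case: a thick-walled curved bone arch, an adjacent soft-tissue tumor
#' eroding the cortex down to a thin residual wall (a partial-volume
#' challenge once the volume is degraded), and thin undulating nerve canals
#' whose intensity is too close to soft tissue for reliable thresholding.
#' Tissue intensities are plausible CT Hounsfield units (air -1000, soft
#' tissue 40, tumor 60, nerve canal 20, cancellous bone 300, cortical bone
#' 1200); the tumor ellipsoid is placed so that its clearance to the outer
#' arch surface equals `residual_wall` mm.
#'
#' @param arch_radius centerline radius of the arch, mm.
#' @param tube_radius cross-section (capsule) radius of the arch, mm.
#' @param arch_half_span_deg half angular span of the arch, degrees (0 =
#'   anterior, +y).
#' @param cortical_thickness outer cortical shell thickness, mm.
#' @param tumor_angle_deg arch angle of the tumor center (positive = right).
#' @param tumor_radii ellipsoid semi-axes (tangential, radial, z), mm.
#' @param tumor_z_offset tumor center height above the arch plane, mm.
#' @param residual_wall bone left between tumor and outer surface, mm.
#' @param nerve_radius canal radius, mm.
#' @param nerve_z_offset canal depth below the arch plane, mm.
#' @param nerve_undulation_amp,nerve_undulation_periods sinusoidal z
#'   undulation added to the spline path.
#' @param nerve_span_deg angular span (absolute degrees) of each canal.
#' @param nerve_control_points number of spline control points.
#' @param soft_margin soft-tissue padding around the arch, mm.
#' @param hu named tissue intensities.
#' @param tooth optional dense inclusion: `list(center =, radius =, hu =)`.
#' @return A named list of class `segqa_phantom_params`.
#' @export
phantom_params <- function(arch_radius = 22, tube_radius = 7,
                           arch_half_span_deg = 110,
                           cortical_thickness = 2,
                           tumor_angle_deg = 55,
                           tumor_radii = c(8, 6, 5),
                           tumor_z_offset = 2,
                           residual_wall = 0.8,
                           nerve_radius = 1,
                           nerve_z_offset = -4.5,
                           nerve_undulation_amp = 1,
                           nerve_undulation_periods = 2.5,
                           nerve_span_deg = c(15, 105),
                           nerve_control_points = 6,
                           soft_margin = 4,
                           hu = c(background = -1000, soft = 40, tumor = 60,
                                  nerve = 20, cancellous = 300,
                                  cortical = 1200),
                           tooth = NULL) {
  p <- as.list(environment())
  structure(p, class = "segqa_phantom_params")
}

#' Default phantom grid
#'
#' A grid large enough to hold the arch plus soft-tissue margin, centered on
#' the world origin.  The default spacing echoes clinical CT geometry:
#' anisotropic voxels with sub-mm in-plane pixels and 1 mm slices.
#'
#' @param params a [phantom_params()].
#' @param spacing voxel spacing, mm.
#' @return A [grid_spec()].
#' @export
default_phantom_grid <- function(params = phantom_params(),
                                 spacing = c(0.33, 0.33, 1)) {
  half_xy <- params$arch_radius + params$tube_radius + params$soft_margin + 2
  half_z <- params$tube_radius + params$soft_margin + 2
  n <- c(2 * ceiling(half_xy / spacing[1]) + 1,
         2 * ceiling(half_xy / spacing[2]) + 1,
         2 * ceiling(half_z / spacing[3]) + 1)
  grid_spec(n, spacing, origin = -(n - 1) / 2 * spacing)
}

#' Generate the mandible/tumor/nerve phantom case
#'
#' Builds the HU volume, ground-truth masks (mandible, tumor, nerve_left,
#' nerve_right) and caliper landmarks for the synthetic study case.  The
#' mandible is an arch-shaped capsule with a cortical shell and cancellous
#' interior; the tumor is a full analytic ellipsoid carved out of the arch so
#' that only `residual_wall` mm of bone separates it from the outer surface;
#' the nerve canals follow a cubic-spline path with sinusoidal undulation.
#' Generation is fully deterministic: identical `params` (and grid) always
#' produce bit-identical output; `seed` is stored for downstream degradation.
#'
#' @param params a [phantom_params()].
#' @param grid a [grid_spec()]; default [default_phantom_grid()].
#' @param seed integer stored with the case and used by stages that add
#'   noise.
#' @param extra_landmarks named list of length-3 world-mm points to add.
#' @param extra_pairs list of length-2 character vectors naming additional
#'   caliper pairs.
#' @return A list of class `segqa_phantom` with elements `volume`,
#'   `truth_masks`, `truth_landmarks` (matrix), `caliper_pairs` (data frame
#'   with ground-truth mm), `params`, `grid`, `seed`.
#' @export
make_mandible_phantom <- function(params = phantom_params(), grid = NULL,
                                  seed = 1L, extra_landmarks = NULL,
                                  extra_pairs = NULL) {
  stopifnot(inherits(params, "segqa_phantom_params"))
  if (is.null(grid)) grid <- default_phantom_grid(params)
  if (params$residual_wall < min(grid$spacing))
    warning(sprintf(
      "residual wall (%.3g mm) is thinner than one voxel (%.3g mm); it may not be resolved",
      params$residual_wall, min(grid$spacing)))

  R <- params$arch_radius
  a <- params$tube_radius
  half <- params$arch_half_span_deg
  shell <- params$cortical_thickness
  hu <- params$hu

  g <- world_grid(list(data = array(0, grid$dim), spacing = grid$spacing,
                       origin = grid$origin))
  rho <- sqrt(g$x^2 + g$y^2)
  theta <- atan2(g$x, g$y) * 180 / pi  # 0 deg = anterior (+y)

  # arch capsule: tube around the arc for |theta| <= half, spherical caps
  d2 <- (rho - R)^2 + g$z^2
  end_r <- c(R * sinpi(half / 180), R * cospi(half / 180), 0)
  d2_end_r <- (g$x - end_r[1])^2 + (g$y - end_r[2])^2 + g$z^2
  d2_end_l <- (g$x + end_r[1])^2 + (g$y - end_r[2])^2 + g$z^2
  in_span <- abs(theta) <= half
  dist2 <- ifelse(in_span, d2, pmin(d2_end_r, d2_end_l))
  tube <- dist2 <= a^2
  cortical <- tube & dist2 >= (a - shell)^2

  # tumor ellipsoid in (tangential, radial, z) frame at the arch wall
  rt <- params$tumor_radii[1]
  rr <- params$tumor_radii[2]
  rz <- params$tumor_radii[3]
  th_t <- params$tumor_angle_deg
  delta <- a - params$residual_wall - rr
  cen <- c((R + delta) * sinpi(th_t / 180), (R + delta) * cospi(th_t / 180),
           params$tumor_z_offset)
  ut <- c(cospi(th_t / 180), -sinpi(th_t / 180), 0)
  ur <- c(sinpi(th_t / 180), cospi(th_t / 180), 0)
  dx <- g$x - cen[1]; dy <- g$y - cen[2]; dz <- g$z - cen[3]
  e1 <- (dx * ut[1] + dy * ut[2]) / rt
  e2 <- (dx * ur[1] + dy * ur[2]) / rr
  e3 <- dz / rz
  tumor <- e1^2 + e2^2 + e3^2 <= 1
  if (!any(tumor & tube))
    stop("tumor does not intersect the mandibular arch wall; ",
         "the case must reproduce the bone-tumor interface")

  # nerve canals: spline path z(theta) with sinusoidal undulation
  nerve_mask <- function(sign) {
    sp <- params$nerve_span_deg
    ctrl_th <- seq(sp[1], sp[2], length.out = params$nerve_control_points)
    ctrl_z <- rep(params$nerve_z_offset, length(ctrl_th))
    fz <- splinefun(ctrl_th, ctrl_z, method = "natural")
    th_abs <- sign * theta
    sel <- th_abs >= sp[1] & th_abs <= sp[2] & abs(rho - R) <= params$nerve_radius
    nz <- array(NA_real_, grid$dim)
    und <- params$nerve_undulation_amp *
      sinpi(2 * params$nerve_undulation_periods *
              (th_abs[sel] - sp[1]) / (sp[2] - sp[1]))
    nz[sel] <- fz(th_abs[sel]) + und
    m <- array(FALSE, grid$dim)
    m[sel] <- (rho[sel] - R)^2 + (g$z[sel] - nz[sel])^2 <= params$nerve_radius^2
    m
  }
  nerve_r <- nerve_mask(+1)
  nerve_l <- nerve_mask(-1)

  # soft-tissue slab surrounding the arch
  soft <- rho <= R + a + params$soft_margin &
    abs(g$z) <= a + params$soft_margin

  vol <- array(hu[["background"]], grid$dim)
  vol[soft] <- hu[["soft"]]
  vol[tube] <- hu[["cancellous"]]
  vol[cortical] <- hu[["cortical"]]
  vol[tumor] <- hu[["tumor"]]
  vol[nerve_r | nerve_l] <- hu[["nerve"]]
  tooth <- NULL
  if (!is.null(params$tooth)) {
    tt <- params$tooth
    d2t <- (g$x - tt$center[1])^2 + (g$y - tt$center[2])^2 +
      (g$z - tt$center[3])^2
    tooth <- d2t <= tt$radius^2
    vol[tooth] <- tt$hu %||% 2000
  }

  mandible <- tube & !tumor & !nerve_r & !nerve_l
  if (!is.null(tooth)) mandible <- mandible & !tooth

  lm <- rbind(
    UCo_right = c(end_r[1], end_r[2], a - 2),
    UCo_left = c(-end_r[1], end_r[2], a - 2),
    Go_right = c(R * sinpi(0.5), R * cospi(0.5), -(a - 2)),
    Go_left = c(-R * sinpi(0.5), R * cospi(0.5), -(a - 2)),
    Me = c(0, R, -(a - 2)),
    AC = c(0, R, a - 2),
    tumor_center = cen
  )
  colnames(lm) <- c("x", "y", "z")
  if (!is.null(extra_landmarks)) {
    add <- do.call(rbind, extra_landmarks)
    rownames(add) <- names(extra_landmarks)
    colnames(add) <- c("x", "y", "z")
    lm <- rbind(lm, add)
  }
  pairs <- list(c("UCo_right", "Go_right"), c("UCo_left", "Go_left"),
                c("Me", "AC"), c("Go_right", "Go_left"),
                c("tumor_center", "Me"))
  if (!is.null(extra_pairs)) pairs <- c(pairs, extra_pairs)
  cp <- data.frame(a = vapply(pairs, `[`, "", 1),
                   b = vapply(pairs, `[`, "", 2))
  cp$truth_mm <- sqrt(rowSums((lm[cp$a, , drop = FALSE] -
                                 lm[cp$b, , drop = FALSE])^2))

  spacing <- grid$spacing
  origin <- grid$origin
  structure(list(
    volume = image_volume(vol, spacing, origin),
    truth_masks = list(
      mandible = binary_mask(mandible, spacing, origin),
      tumor = binary_mask(tumor, spacing, origin),
      nerve_left = binary_mask(nerve_l, spacing, origin),
      nerve_right = binary_mask(nerve_r, spacing, origin)
    ),
    truth_landmarks = lm,
    caliper_pairs = cp,
    params = params,
    grid = grid,
    seed = as.integer(seed)
  ), class = "segqa_phantom")
}

#' @export
print.segqa_phantom <- function(x, ...) {
  cat("<segqa_phantom> mandible/tumor/nerve case\n")
  print(x$volume)
  vols <- vapply(x$truth_masks, mask_volume_mm3, 0)
  cat("  truth masks (mm^3):",
      paste(sprintf("%s=%.0f", names(vols), vols), collapse = ", "), "\n")
  cat(sprintf("  %d landmarks, %d caliper pairs, seed %d\n",
              nrow(x$truth_landmarks), nrow(x$caliper_pairs), x$seed))
  invisible(x)
}

# separable Gaussian blur along one axis, sigma in voxels; truncated at 4
# sigma with per-row renormalization so the local mean is conserved
blur_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  n <- dim(arr)[axis]
  half <- max(1L, ceiling(4 * sigma))
  off <- (-half):half
  k <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(off)) {
    src <- idx + off[j]
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[j]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  dp <- dim(ap)
  res <- K %*% matrix(ap, nrow = n)
  aperm(array(res, dp), order(perm))
}

trilinear_resample <- function(vol, target_spacing) {
  d <- dim(vol$data)
  ext <- (d - 1) * vol$spacing
  nd <- pmax(2L, floor(ext / target_spacing) + 1L)
  # index-space (0-based) coordinates of new voxel centers in the old grid
  coord <- lapply(1:3, function(a)
    (seq_len(nd[a]) - 1) * target_spacing[a] / vol$spacing[a])
  cx <- coord[[1]]; cy <- coord[[2]]; cz <- coord[[3]]
  fx <- pmin(floor(cx) + 1, d[1] - 1); tx <- cx - (fx - 1)
  fy <- pmin(floor(cy) + 1, d[2] - 1); ty <- cy - (fy - 1)
  fz <- pmin(floor(cz) + 1, d[3] - 1); tz <- cz - (fz - 1)
  TX <- array(rep(tx, times = nd[2] * nd[3]), nd)
  TY <- array(rep(rep(ty, each = nd[1]), times = nd[3]), nd)
  TZ <- array(rep(tz, each = nd[1] * nd[2]), nd)
  gather <- function(ix, iy, iz)
    array(vol$data[cbind(rep(ix, times = nd[2] * nd[3]),
                         rep(rep(iy, each = nd[1]), times = nd[3]),
                         rep(iz, each = nd[1] * nd[2]))], nd)
  out <-
    gather(fx, fy, fz) * (1 - TX) * (1 - TY) * (1 - TZ) +
    gather(fx + 1, fy, fz) * TX * (1 - TY) * (1 - TZ) +
    gather(fx, fy + 1, fz) * (1 - TX) * TY * (1 - TZ) +
    gather(fx + 1, fy + 1, fz) * TX * TY * (1 - TZ) +
    gather(fx, fy, fz + 1) * (1 - TX) * (1 - TY) * TZ +
    gather(fx + 1, fy, fz + 1) * TX * (1 - TY) * TZ +
    gather(fx, fy + 1, fz + 1) * (1 - TX) * TY * TZ +
    gather(fx + 1, fy + 1, fz + 1) * TX * TY * TZ
  image_volume(out, target_spacing, vol$origin)
}

#' Degrade a phantom volume towards clinical image quality
#'
#' Models the acquisition chain that blurs thin structures: Gaussian
#' point-spread blur of the stated full width at half maximum, optional
#' resampling to a coarser grid (linear interpolation), then additive
#' Gaussian noise.  Partial-volume averaging is the blur + resample
#' combination: intensities of adjacent tissues mix within a voxel, eroding
#' extreme values such as thin cortical bone.
#'
#' @param vol an [image_volume()].
#' @param psf_fwhm_mm per-axis blur FWHM in mm (scalar recycled); >= 0.
#' @param noise_sd additive Gaussian noise standard deviation, HU; >= 0.
#' @param target_spacing optional coarser spacing to resample to, mm.
#' @param seed RNG seed for the noise.
#' @return An [image_volume()].
#' @export
degrade <- function(vol, psf_fwhm_mm = 0, noise_sd = 0,
                    target_spacing = NULL, seed = 1L) {
  stopifnot(inherits(vol, "segqa_volume"))
  psf_fwhm_mm <- rep_len(psf_fwhm_mm, 3)
  if (any(psf_fwhm_mm < 0)) stop("psf_fwhm_mm must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(target_spacing)) {
    target_spacing <- rep_len(target_spacing, 3)
    if (any(target_spacing < vol$spacing - 1e-12))
      stop("target spacing is finer than the source spacing; ",
           "resolution cannot be fabricated")
  }
  sigma_vox <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / vol$spacing
  data <- vol$data
  for (axis in 1:3) data <- blur_axis(data, sigma_vox[axis], axis)
  out <- image_volume(data, vol$spacing, vol$origin)
  if (!is.null(target_spacing) &&
      any(abs(target_spacing - vol$spacing) > 1e-12))
    out <- trilinear_resample(out, target_spacing)
  if (noise_sd > 0) {
    set.seed(seed)
    out$data <- out$data + array(rnorm(length(out$data), 0, noise_sd),
                                 dim(out$data))
  }
  out
}
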
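#' Enclosed volume and surface area of a mesh
#'
#' `mesh_volume()` is the divergence-theorem (signed tetrahedron) sum,
#' positive for outward-oriented watertight meshes; it refuses open meshes
#' because volumes can only be calculated on closed surfaces.
#' `mesh_area()` is the plain sum of triangle areas and works on any mesh.
#'
#' @param x a [mesh()].
#' @return Volume in mm^3 / area in mm^2.
#' @examples
#' cube <- extract_surface(
#'   make_primitive("box", grid_spec(c(4, 4, 4), c(1, 1, 1)),
#'                  lo = c(0, 0, 0), hi = c(3, 3, 3)))
#' mesh_volume(cube)
#' mesh_area(cube)
#' @export
mesh_volume <- function(x) {
  stopifnot(inherits(x, "segqa_mesh"))
  dg <- mesh_diagnostics(x)
  if (!dg$watertight)
    stop("volumes can only be calculated on closed surfaces ",
         "(mesh_diagnostics: ", dg$n_faces, " faces, not every edge is ",
         "shared by exactly 2 faces)")
  # consistent orientation: every undirected edge traversed once per direction
  e <- rbind(x$faces[, 1:2], x$faces[, 2:3], x$faces[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key))
    stop("mesh is not consistently oriented")
  v1 <- x$vertices[x$faces[, 1], , drop = FALSE]
  v2 <- x$vertices[x$faces[, 2], , drop = FALSE]
  v3 <- x$vertices[x$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
        v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
        v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(x) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (nrow(x$faces) == 0) return(0)
  v1 <- x$vertices[x$faces[, 1], , drop = FALSE]
  n <- cross3(x$vertices[x$faces[, 2], , drop = FALSE] - v1,
              x$vertices[x$faces[, 3], , drop = FALSE] - v1)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Voxelize a watertight mesh
#'
#' Rasterizes the solid bounded by the mesh on an isotropic grid of the
#' given pitch: a voxel is true iff its center lies inside the surface
#' (ray-parity test).  The grid covers the mesh bounding box padded by one
#' voxel.
#'
#' @param x a watertight [mesh()].
#' @param pitch voxel edge length, mm.
#' @param bbox optional 2 x 3 matrix (rows lo, hi) overriding the grid
#'   extent, e.g. to voxelize several meshes on one common grid.
#' @return A [binary_mask()].
#' @export
voxelize_mesh <- function(x, pitch, bbox = NULL) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (pitch <= 0) stop("pitch must be > 0")
  dg <- mesh_diagnostics(x)
  if (!dg$watertight)
    stop("voxelization requires a watertight mesh")
  if (is.null(bbox)) bbox <- dg$bbox
  lo <- bbox[1, ] - pitch
  n <- pmax(2L, as.integer(ceiling((bbox[2, ] - lo) / pitch)) + 2L)
  data <- array(.voxelize_cpp(x$vertices, x$faces, lo, pitch, n), n)
  binary_mask(data, rep(pitch, 3), lo)
}

#' Volumetric agreement and disagreement between two models
#'
#' Voxelizes both meshes on one common grid and reports intersection/union
#' volumes and overlap percentages.  The symmetric variant normalizes by the
#' union: agreement = 100 V(A&B)/V(A|B), disagreement = 100 (V(A|B) -
#' V(A&B))/V(A|B), so the two always sum to exactly 100.  The
#' `relative_to_a` variant normalizes by model A: agreement = 100
#' V(A&B)/V(A), disagreement = 100 V(A\\B)/V(A) — asymmetric, suitable for
#' filling a pairwise matrix against a reference model.  Meshes must share a
#' world frame (true by construction within one pipeline run; no
#' registration is performed).
#'
#' @param a,b watertight [mesh()]es in the same world frame.
#' @param pitch voxelization pitch, mm.
#' @param variant `"symmetric"` (default) or `"relative_to_a"`.
#' @return A list of class `segqa_overlap`: `v_a`, `v_b`, `v_intersection`,
#'   `v_union`, `v_only_a`, `v_only_b` (mm^3), `agreement_pct`,
#'   `disagreement_pct`, `variant`, `voxel_pitch`.
#' @export
agreement_disagreement <- function(a, b, pitch = 0.2,
                                   variant = c("symmetric", "relative_to_a")) {
  variant <- match.arg(variant)
  bbox <- rbind(pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min)),
                pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max)))
  ma <- voxelize_mesh(a, pitch, bbox)
  mb <- voxelize_mesh(b, pitch, bbox)
  overlap_from_masks(ma$data, mb$data, pitch, variant)
}

overlap_from_masks <- function(da, db, pitch, variant) {
  vv <- pitch^3
  n_a <- sum(da); n_b <- sum(db)
  if (n_a == 0 || n_b == 0)
    stop("empty voxelization at pitch ", pitch, " mm; use a finer pitch")
  n_int <- sum(da & db)
  n_uni <- n_a + n_b - n_int
  res <- list(
    v_a = n_a * vv, v_b = n_b * vv,
    v_intersection = n_int * vv, v_union = n_uni * vv,
    v_only_a = (n_a - n_int) * vv, v_only_b = (n_b - n_int) * vv,
    variant = variant, voxel_pitch = pitch)
  if (variant == "symmetric") {
    res$agreement_pct <- 100 * n_int / n_uni
    res$disagreement_pct <- 100 * (n_uni - n_int) / n_uni
  } else {
    res$agreement_pct <- 100 * n_int / n_a
    res$disagreement_pct <- 100 * (n_a - n_int) / n_a
  }
  structure(res, class = "segqa_overlap")
}

#' @export
print.segqa_overlap <- function(x, ...) {
  cat(sprintf(
    "<segqa_overlap> (%s, pitch %g mm)\n  V(A) = %.2f, V(B) = %.2f, V(A&B) = %.2f, V(A|B) = %.2f mm^3\n  agreement %.1f%%, disagreement %.1f%%\n",
    x$variant, x$voxel_pitch, x$v_a, x$v_b, x$v_intersection, x$v_union,
    x$agreement_pct, x$disagreement_pct))
  invisible(x)
}

#' Pairwise overlap matrices for a set of models
#'
#' Voxelizes every mesh once on a single common grid and fills the pairwise
#' agreement and disagreement matrices (the intersection-matrix view of a
#' model set).
#'
#' @param meshes named list of watertight [mesh()]es in one world frame.
#' @param pitch voxelization pitch, mm.
#' @param variant as in [agreement_disagreement()].
#' @return A list with `agreement` and `disagreement` percent matrices and
#'   `volumes_mm3`.
#' @export
overlap_matrix <- function(meshes, pitch = 0.2,
                           variant = c("symmetric", "relative_to_a")) {
  variant <- match.arg(variant)
  stopifnot(length(meshes) >= 2)
  nm <- names(meshes) %||% paste0("m", seq_along(meshes))
  los <- sapply(meshes, function(m) apply(m$vertices, 2, min))
  his <- sapply(meshes, function(m) apply(m$vertices, 2, max))
  bbox <- rbind(apply(los, 1, min), apply(his, 1, max))
  vox <- lapply(meshes, voxelize_mesh, pitch = pitch, bbox = bbox)
  k <- length(meshes)
  agree <- disagree <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(agree) <- 100
  diag(disagree) <- 0
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    if (variant == "symmetric" && j < i) {
      agree[i, j] <- agree[j, i]
      disagree[i, j] <- disagree[j, i]
      next
    }
    ov <- overlap_from_masks(vox[[i]]$data, vox[[j]]$data, pitch, variant)
    agree[i, j] <- ov$agreement_pct
    disagree[i, j] <- ov$disagreement_pct
  }
  list(agreement = agree, disagreement = disagree,
       volumes_mm3 = vapply(vox, mask_volume_mm3, 0),
       voxel_pitch = pitch, variant = variant)
}

# area-weighted uniform sampling of points on a mesh surface
sample_surface <- function(x, n) {
  if (n <= 0) return(NULL)
  v1 <- x$vertices[x$faces[, 1], , drop = FALSE]
  v2 <- x$vertices[x$faces[, 2], , drop = FALSE]
  v3 <- x$vertices[x$faces[, 3], , drop = FALSE]
  areas <- sqrt(rowSums(cross3(v2 - v1, v3 - v1)^2)) / 2
  f <- sample.int(nrow(x$faces), n, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n))
  r2 <- runif(n)
  (1 - r1) * v1[f, , drop = FALSE] + r1 * (1 - r2) * v2[f, , drop = FALSE] +
    r1 * r2 * v3[f, , drop = FALSE]
}

directed_summary <- function(P, target, signed_target_watertight) {
  d <- .closest_tri_dist_cpp(P, target$vertices, target$faces)
  if (signed_target_watertight) {
    inside <- .points_in_mesh_cpp(P, target$vertices, target$faces)
    d <- ifelse(inside, -d, d)
  }
  d
}

#' Signed surface deviation field between two models
#'
#' Samples surface A (all vertices plus optional area-uniform extra samples)
#' and measures, for each sample, the exact distance to the closest point on
#' any triangle of surface B — the point-to-surface field behind deviation
#' heatmaps.  The sign is negative where the sample lies inside B (positive
#' deviation = A outside B).  Summaries include the directed Hausdorff
#' distances in both directions, the symmetric Hausdorff (their maximum),
#' mean absolute deviation, RMS and the 95th percentile.
#'
#' @param a,b [mesh()]es in one world frame.
#' @param samples_per_mm2 extra sample density on each surface (0 = vertices
#'   only).
#' @param signed request signed distances; needs watertight meshes (falls
#'   back to unsigned with a warning otherwise).
#' @param seed RNG seed for the area-uniform sampling.
#' @return A list of class `segqa_deviation`: `sample_points`, `signed_d`
#'   (per point on A), `directed_ab`, `directed_ba`, `hausdorff`,
#'   `mean_abs`, `rms`, `p95`, `signed`.
#' @export
deviation_field <- function(a, b, samples_per_mm2 = 1, signed = TRUE,
                            seed = 1L) {
  stopifnot(inherits(a, "segqa_mesh"), inherits(b, "segqa_mesh"))
  sign_ok_b <- signed && mesh_diagnostics(b)$watertight
  sign_ok_a <- signed && mesh_diagnostics(a)$watertight
  if (signed && (!sign_ok_b || !sign_ok_a)) {
    warning("signed deviation requested but a mesh is not watertight; ",
            "falling back to unsigned distances")
    sign_ok_a <- sign_ok_b <- FALSE
  }
  set.seed(seed)
  Pa <- rbind(a$vertices,
              sample_surface(a, ceiling(samples_per_mm2 * mesh_area(a))))
  Pb <- rbind(b$vertices,
              sample_surface(b, ceiling(samples_per_mm2 * mesh_area(b))))
  d_ab <- directed_summary(Pa, b, sign_ok_b)
  d_ba <- directed_summary(Pb, a, sign_ok_a)
  abs_ab <- abs(d_ab)
  structure(list(
    sample_points = Pa,
    signed_d = d_ab,
    directed_ab = max(abs_ab),
    directed_ba = max(abs(d_ba)),
    hausdorff = max(max(abs_ab), max(abs(d_ba))),
    mean_abs = mean(abs_ab),
    rms = sqrt(mean(abs_ab^2)),
    p95 = unname(stats::quantile(abs_ab, 0.95)),
    signed = sign_ok_b
  ), class = "segqa_deviation")
}

#' @export
print.segqa_deviation <- function(x, ...) {
  cat(sprintf(
    "<segqa_deviation> %d samples (%ssigned)\n  Hausdorff %.3f mm (A->B %.3f, B->A %.3f), mean |d| %.3f, RMS %.3f, p95 %.3f mm\n",
    length(x$signed_d), if (x$signed) "" else "un",
    x$hausdorff, x$directed_ab, x$directed_ba, x$mean_abs, x$rms, x$p95))
  invisible(x)
}

#' @export
plot.segqa_deviation <- function(x, ...) {
  hist(x$signed_d, breaks = 50, main = "surface deviation",
       xlab = "signed distance to B (mm)", ...)
  invisible(x)
}

#' Attach a deviation field to its source mesh as a heatmap channel
#'
#' Writes the per-vertex signed deviations of `deviation_field(a, b)` into
#' `a`'s scalar channel (vertex samples come first in the field), ready for
#' [write_ply()].
#'
#' @param a the source mesh of the deviation field.
#' @param dev a `segqa_deviation` computed from `a`.
#' @return `a` with a populated scalar channel.
#' @export
deviation_heatmap <- function(a, dev) {
  stopifnot(inherits(dev, "segqa_deviation"))
  mesh(a$vertices, a$faces, scalar = dev$signed_d[seq_len(nrow(a$vertices))])
}
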
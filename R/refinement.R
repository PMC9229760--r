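# vertex adjacency as a sparse row-stochastic averaging operator; boundary
# vertices (edges with a single incident face) are frozen during smoothing
smooth_operator <- function(x) {
  e <- rbind(x$faces[, 1:2], x$faces[, 2:3], x$faces[, c(3, 1)])
  und <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(und[, 1], und[, 2])
  cnt <- table(key)
  boundary_edges <- und[!duplicated(key), , drop = FALSE][cnt[unique(key)] == 1, ,
                                                          drop = FALSE]
  frozen <- unique(as.vector(boundary_edges))
  uu <- und[!duplicated(key), , drop = FALSE]
  nv <- nrow(x$vertices)
  A <- Matrix::sparseMatrix(i = c(uu[, 1], uu[, 2]), j = c(uu[, 2], uu[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  list(A = A, deg = deg, frozen = frozen)
}

smooth_steps <- function(x, iterations, lams) {
  if (iterations == 0 || nrow(x$faces) == 0) return(x)
  op <- smooth_operator(x)
  V <- x$vertices
  for (it in seq_len(iterations)) {
    for (lam in lams) {
      if (lam == 0) next
      cen <- as.matrix(op$A %*% V) / op$deg
      Vn <- V + lam * (cen - V)
      if (length(op$frozen)) Vn[op$frozen, ] <- V[op$frozen, ]
      V <- Vn
    }
  }
  mesh(V, x$faces, x$scalar)
}

#' Laplacian mesh smoothing
#'
#' The canonical umbrella-operator smoother: each iteration moves every
#' vertex toward the centroid of its 1-ring neighbors by a factor `lam`
#' (uniform weights, synchronous update).  Smooths but shrinks closed
#' meshes; connectivity is never changed.
#'
#' @param x a [mesh()] (connectivity required, i.e. merged vertices).
#' @param iterations number of passes, >= 0 (0 is the identity).
#' @param lam step factor in (0, 1].
#' @return A [mesh()] with the same faces and moved vertices.
#' @export
laplacian_smooth <- function(x, iterations, lam = 0.5) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (iterations < 0) stop("iterations must be >= 0")
  if (lam <= 0 || lam > 1) stop("lam must be in (0, 1]")
  smooth_steps(x, iterations, lams = lam)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternates a Laplacian shrink step (`lam` > 0) with a compensating
#' inflation step (`mu` < 0) each iteration, approximating a low-pass filter
#' that smooths without net shrinkage.  The pass-band condition requires
#' `0 < lam < 1`, `-1 < mu < 0` and `|mu| > lam`.
#'
#' @param x a [mesh()].
#' @param iterations number of lambda+mu iterations, >= 0.
#' @param lam shrink step in (0, 1).
#' @param mu inflation step in (-1, 0) with `|mu| > lam`.
#' @return A [mesh()].
#' @export
taubin_smooth <- function(x, iterations, lam = 0.33, mu = -0.34) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (iterations < 0) stop("iterations must be >= 0")
  if (lam <= 0 || lam >= 1) stop("pass-band condition violated: lam must be in (0, 1)")
  if (mu <= -1 || mu >= 0) stop("pass-band condition violated: mu must be in (-1, 0)")
  if (abs(mu) <= lam) stop("pass-band condition violated: |mu| must exceed lam")
  smooth_steps(x, iterations, lams = c(lam, mu))
}

#' Topology-preserving mesh decimation
#'
#' Reduces the face count by iterative edge collapse ordered by quadric
#' error, refusing any collapse that would break the manifold link
#' condition, flip a surviving face, or push the cumulative enclosed-volume
#' drift past `volume_tol`, so watertight inputs stay watertight and keep
#' their volume.  Coarse meshes whose every collapse would distort the shape
#' (a 12-face box) therefore come back unchanged with a warning.
#'
#' @param x a [mesh()]; non-watertight inputs are processed with a warning
#'   (and without the volume gate).
#' @param target_fraction requested face-count fraction in (0, 1].
#' @param volume_tol relative enclosed-volume budget for the whole
#'   decimation (closed meshes only).
#' @return A [mesh()] with at most `ceiling(target_fraction * n_faces)`
#'   faces when enough valid collapses exist; if topology prevents reaching
#'   the target a warning reports the achieved count.
#' @export
decimate_mesh <- function(x, target_fraction, volume_tol = 0.02) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  if (target_fraction == 1) return(x)
  dg <- mesh_diagnostics(x)
  if (!dg$watertight)
    warning("mesh is not watertight; decimating anyway")
  target <- as.integer(ceiling(target_fraction * nrow(x$faces)))
  if (dg$watertight && target < 4)
    stop("target_fraction implies fewer than 4 faces on a closed mesh")
  v0 <- if (dg$watertight) mesh_volume(x) else NA_real_
  budget <- if (is.na(v0)) 0 else volume_tol * abs(v0)
  res <- .decimate_qem_cpp(x$vertices, x$faces, target, budget)
  out <- mesh(res$vertices, res$faces)
  if (nrow(out$faces) > target)
    warning(sprintf(
      "could not reach %d faces without topology loss; achieved %d",
      target, nrow(out$faces)))
  if (!is.na(v0) && nrow(out$faces) < nrow(x$faces)) {
    v1 <- mesh_volume(out)
    err <- abs(v1 - v0) / v0
    if (err > volume_tol)
      warning(sprintf("decimation changed the enclosed volume by %.2f%%", 100 * err))
    attr(out, "volume_error") <- err
  }
  out
}

#' Apply a profile's smoothing level to a mesh
#'
#' Level 0 returns the input unchanged; levels 1 and 2 dispatch to the
#' profile's smoothing algorithm with the level's iteration count, followed
#' by the profile's optional decimation.
#'
#' @param x a [mesh()].
#' @param profile a [workflow_profile()].
#' @param level 0, 1 or 2.
#' @return A [mesh()].
#' @export
apply_smoothing_level <- function(x, profile, level) {
  stopifnot(inherits(x, "segqa_mesh"), inherits(profile, "segqa_profile"))
  if (!level %in% 0:2)
    stop("smoothing level must be 0, 1 or 2")
  if (level == 0) return(x)
  sm <- profile$smoothing
  iters <- sm$iterations[level + 1]
  out <- switch(sm$algorithm,
    none = x,
    laplacian = laplacian_smooth(x, iters, sm$lambda),
    taubin = taubin_smooth(x, iters, sm$lambda, sm$mu),
    stop("unknown smoothing algorithm: ", sm$algorithm))
  if (!is.null(profile$decimation))
    out <- decimate_mesh(out, profile$decimation)
  out
}
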
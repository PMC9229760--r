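#' Virtual caliper distances between named landmarks
#'
#' Euclidean distances between pairs of fiduciary points, the way linear
#' mandible measurements are taken with virtual calipers.
#'
#' @param landmarks named matrix (rows = landmarks, 3 columns, mm) or named
#'   list of length-3 points.
#' @param pairs list of length-2 character vectors, or a 2-column matrix /
#'   data frame of names.
#' @return A data frame with columns `a`, `b`, `distance_mm`.
#' @examples
#' lm <- rbind(p = c(0, 0, 0), q = c(3, 4, 0))
#' landmark_distance(lm, list(c("p", "q")))  # 5
#' @export
landmark_distance <- function(landmarks, pairs) {
  if (is.list(landmarks) && !is.matrix(landmarks))
    landmarks <- do.call(rbind, landmarks)
  if (is.data.frame(pairs) || is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  nm <- rownames(landmarks)
  want <- unique(unlist(pairs))
  missing <- setdiff(want, nm)
  if (length(missing))
    stop("unknown landmark(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(nm, collapse = ", "))
  a <- vapply(pairs, `[`, "", 1)
  b <- vapply(pairs, `[`, "", 2)
  d <- sqrt(rowSums((landmarks[a, , drop = FALSE] -
                       landmarks[b, , drop = FALSE])^2))
  data.frame(a = a, b = b, distance_mm = unname(d))
}

# orthonormal in-plane basis for a unit axis
plane_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  e <- diag(3)[, which.min(abs(axis))]
  u <- c(axis[2] * e[3] - axis[3] * e[2],
         axis[3] * e[1] - axis[1] * e[3],
         axis[1] * e[2] - axis[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v, axis = axis)
}

# chain unordered segments (pairs of 2-D points) into closed polyline loops
chain_loops <- function(p1, p2, tol) {
  pts <- rbind(p1, p2)
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol))
  uid <- match(key, unique(key))
  n <- nrow(p1)
  a <- uid[seq_len(n)]
  b <- uid[n + seq_len(n)]
  keep <- a != b  # drop degenerate (tangent) segments
  a <- a[keep]; b <- b[keep]
  upts <- pts[!duplicated(uid), , drop = FALSE]
  adj <- vector("list", nrow(upts))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], i)
    adj[[b[i]]] <- c(adj[[b[i]]], i)
  }
  used <- rep(FALSE, length(a))
  loops <- list()
  for (s in seq_along(a)) {
    if (used[s]) next
    used[s] <- TRUE
    loop <- c(a[s], b[s])
    repeat {
      cur <- loop[length(loop)]
      nxt_seg <- setdiff(adj[[cur]], which(used))
      if (!length(nxt_seg)) break
      seg <- nxt_seg[1]
      used[seg] <- TRUE
      nxt <- if (a[seg] == cur) b[seg] else a[seg]
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- upts[loop, , drop = FALSE]
  }
  loops
}

poly_area_centroid <- function(loop) {
  x <- loop[, 1]; y <- loop[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12)
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  list(area = A, centroid = c(cx, cy))
}

point_in_poly <- function(p, loop) {
  x <- loop[, 1]; y <- loop[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crossing <- ((y > p[2]) != (yn > p[2])) &
    (p[1] < (xn - x) * (p[2] - y) / (yn - y) + x)
  sum(crossing) %% 2 == 1
}

#' Slice a mesh with parallel datum planes
#'
#' Cuts the mesh with `n_planes` parallel planes perpendicular to `axis`.
#' With automatic placement the planes sit at fractions i/(n+1) of the
#' mesh's extent along the axis (the end caps are excluded to avoid tangent
#' degeneracies).  Triangle-plane intersection segments are chained into
#' closed loops; loops are classified outer/hole by containment nesting
#' depth, and areas and area-weighted centroids are reported with holes
#' subtracting.
#'
#' @param x a [mesh()].
#' @param axis plane normal (any non-zero vector; normalized internally).
#' @param n_planes number of planes, >= 1 (ignored when `offsets` given).
#' @param offsets optional explicit plane offsets along the unit axis, mm.
#' @return A list of `segqa_slice` objects, one per plane, each with
#'   `plane` (axis + offset), `loops` (world-mm closed polylines),
#'   `area_mm2` (per-loop signed: holes negative), `total_area_mm2`,
#'   `centroid` (world mm, NA for empty slices), `u`, `v` (in-plane basis)
#'   and `empty` flag.
#' @export
slice_mesh <- function(x, axis = c(0, 0, 1), n_planes = 1, offsets = NULL) {
  stopifnot(inherits(x, "segqa_mesh"))
  if (sqrt(sum(axis^2)) == 0) stop("axis must be a non-zero vector")
  bs <- plane_basis(axis)
  t_all <- x$vertices %*% bs$axis
  if (is.null(offsets)) {
    if (n_planes < 1) stop("n_planes must be >= 1")
    lo <- min(t_all); hi <- max(t_all)
    offsets <- lo + (hi - lo) * seq_len(n_planes) / (n_planes + 1)
  }
  scale <- max(apply(x$vertices, 2, function(cc) diff(range(cc))), 1e-9)
  tol <- 1e-7 * scale
  pu <- x$vertices %*% bs$u
  pv <- x$vertices %*% bs$v
  lapply(offsets, function(off) {
    s <- as.vector(t_all) - off
    s[s == 0] <- tol * 1e-3  # nudge exact vertex contacts off the plane
    sgn <- s > 0
    f <- x$faces
    cross_edges <- function(i, j) sgn[f[, i]] != sgn[f[, j]]
    c12 <- cross_edges(1, 2); c23 <- cross_edges(2, 3); c31 <- cross_edges(3, 1)
    hit <- c12 | c23 | c31
    if (!any(hit)) {
      return(structure(list(plane = list(axis = bs$axis, offset = off),
                            loops = list(), area_mm2 = numeric(0),
                            total_area_mm2 = 0, centroid = rep(NA_real_, 3),
                            u = bs$u, v = bs$v, empty = TRUE),
                       class = "segqa_slice"))
    }
    fh <- f[hit, , drop = FALSE]
    ipt <- function(i, j) {
      wi <- s[fh[, i]]; wj <- s[fh[, j]]
      tt <- wi / (wi - wj)
      cbind(pu[fh[, i]] + tt * (pu[fh[, j]] - pu[fh[, i]]),
            pv[fh[, i]] + tt * (pv[fh[, j]] - pv[fh[, i]]),
            ifelse(sgn[fh[, i]] != sgn[fh[, j]], 1, NA))
    }
    e12 <- ipt(1, 2); e23 <- ipt(2, 3); e31 <- ipt(3, 1)
    # each crossing triangle has exactly two crossing edges
    seg1 <- matrix(NA_real_, nrow(fh), 2)
    seg2 <- matrix(NA_real_, nrow(fh), 2)
    for (r in seq_len(nrow(fh))) {
      pts <- rbind(if (!is.na(e12[r, 3])) e12[r, 1:2],
                   if (!is.na(e23[r, 3])) e23[r, 1:2],
                   if (!is.na(e31[r, 3])) e31[r, 1:2])
      seg1[r, ] <- pts[1, ]
      seg2[r, ] <- pts[2, ]
    }
    loops <- chain_loops(seg1, seg2, tol)
    if (!length(loops)) {
      return(structure(list(plane = list(axis = bs$axis, offset = off),
                            loops = list(), area_mm2 = numeric(0),
                            total_area_mm2 = 0, centroid = rep(NA_real_, 3),
                            u = bs$u, v = bs$v, empty = TRUE),
                       class = "segqa_slice"))
    }
    ac <- lapply(loops, poly_area_centroid)
    # nesting depth: odd = hole (negative area)
    depth <- vapply(seq_along(loops), function(i) {
      p <- loops[[i]][1, ]
      sum(vapply(seq_along(loops), function(j) {
        j != i && point_in_poly(p, loops[[j]])
      }, TRUE))
    }, 0L)
    sign_fac <- ifelse(depth %% 2 == 0, 1, -1)
    areas <- vapply(ac, function(z) abs(z$area), 0) * sign_fac
    total <- sum(areas)
    cen2 <- if (abs(total) > 1e-12) {
      colSums(do.call(rbind, lapply(ac, `[[`, "centroid")) * areas) / total
    } else c(NA_real_, NA_real_)
    cen3 <- if (anyNA(cen2)) rep(NA_real_, 3) else
      cen2[1] * bs$u + cen2[2] * bs$v + off * bs$axis
    loops3 <- lapply(loops, function(L)
      L[, 1] %o% bs$u + L[, 2] %o% bs$v +
        matrix(off * bs$axis, nrow(L), 3, byrow = TRUE))
    structure(list(plane = list(axis = bs$axis, offset = off),
                   loops = loops3, loops2d = loops,
                   area_mm2 = areas, total_area_mm2 = total,
                   centroid = cen3, u = bs$u, v = bs$v,
                   empty = abs(total) < 1e-12),
              class = "segqa_slice")
  })
}

#' @export
print.segqa_slice <- function(x, ...) {
  cat(sprintf(
    "<segqa_slice> offset %.3f mm: %d loop(s), total area %.3f mm^2\n",
    x$plane$offset, length(x$loops), x$total_area_mm2))
  invisible(x)
}

#' Centroid and directional extents of a planar contour slice
#'
#' The area-weighted centroid over all loops (holes subtract) and the
#' distance from the centroid to the farthest contour intersection along
#' each of the four in-plane ray directions +u, -u, +v, -v — the X/Y
#' "distance to the edges" measurement on a tumor section.  Full widths
#' (`ext_pu + ext_mu`, `ext_pv + ext_mv`) are also reported.
#'
#' @param slice a `segqa_slice` from [slice_mesh()].
#' @param u,v optional in-plane unit axes (default: the slice's own basis).
#' @return A list: `centroid` (world mm), `ext_pu`, `ext_mu`, `ext_pv`,
#'   `ext_mv`, `width_u`, `width_v` (mm).
#' @export
contour_centroid_extents <- function(slice, u = NULL, v = NULL) {
  stopifnot(inherits(slice, "segqa_slice"))
  if (slice$empty || abs(slice$total_area_mm2) < 1e-12)
    stop("slice has zero area; extents are undefined")
  bs_u <- u %||% slice$u
  bs_v <- v %||% slice$v
  bs_u <- bs_u / sqrt(sum(bs_u^2))
  bs_v <- bs_v / sqrt(sum(bs_v^2))
  cen <- slice$centroid
  # farthest contour crossing of the ray {centroid + t * dirvec, t > 0}:
  # in (dirvec, perp) coordinates around the centroid, find where loop
  # segments cross perp = 0 with along > 0
  ray_ext <- function(dirvec) {
    best <- 0
    for (L in slice$loops) {
      P <- sweep(L, 2, cen)
      along <- as.vector(P %*% dirvec)
      # signed perpendicular coordinate: dirvec rotated 90 degrees in-plane
      nrm <- cbind(bs_u, bs_v) %*% c(-sum(dirvec * bs_v), sum(dirvec * bs_u))
      perp <- as.vector(P %*% nrm)
      nxt <- c(seq_len(nrow(L))[-1], 1)
      crossing <- (perp > 0) != (perp[nxt] > 0)
      if (!any(crossing)) next
      i <- which(crossing)
      tt <- perp[i] / (perp[i] - perp[nxt][i])
      a_hit <- along[i] + tt * (along[nxt][i] - along[i])
      a_hit <- a_hit[a_hit > 0]
      if (length(a_hit)) best <- max(best, max(a_hit))
    }
    best
  }
  list(centroid = cen,
       ext_pu = ray_ext(bs_u), ext_mu = ray_ext(-bs_u),
       ext_pv = ray_ext(bs_v), ext_mv = ray_ext(-bs_v),
       width_u = ray_ext(bs_u) + ray_ext(-bs_u),
       width_v = ray_ext(bs_v) + ray_ext(-bs_v))
}

#' Nerve path traces
#'
#' `path_trace()` bundles per-slice centroids of one model's nerve canal;
#' `mesh_path_trace()` builds one by slicing a nerve mesh with parallel
#' planes.  Empty slices are dropped (and must then be dropped consistently
#' across models before comparison).
#'
#' @param model_id model label.
#' @param slice_index integer slice indices, strictly increasing.
#' @param centroids matrix of world-mm centroids, one row per slice.
#' @param side label such as `"healthy"` or `"tumor"`.
#' @return A list of class `segqa_path_trace`.
#' @export
path_trace <- function(model_id, slice_index, centroids, side = "") {
  slice_index <- as.integer(slice_index)
  centroids <- as.matrix(centroids)
  if (is.unsorted(slice_index, strictly = TRUE))
    stop("slice indices must be strictly increasing")
  if (nrow(centroids) != length(slice_index))
    stop("one centroid per slice required")
  structure(list(model_id = model_id, slice_index = slice_index,
                 centroids = centroids, side = side),
            class = "segqa_path_trace")
}

#' @rdname path_trace
#' @param x a nerve [mesh()].
#' @param axis,offsets slicing geometry passed to [slice_mesh()]; `offsets`
#'   must be shared across the models being compared.
#' @export
mesh_path_trace <- function(x, model_id, axis, offsets, side = "") {
  slices <- slice_mesh(x, axis = axis, offsets = offsets)
  keep <- !vapply(slices, `[[`, TRUE, "empty")
  cen <- do.call(rbind, lapply(slices[keep], `[[`, "centroid"))
  path_trace(model_id, which(keep), cen, side)
}

#' Compare nerve-path centroids across models
#'
#' For every slice, the mean centroid over all models is computed and each
#' model's distance to that mean is reported — the per-slice deviation
#' measure for stacked nerve models.  Per-model aggregates (mean over
#' slices) feed the ANOVA/Tukey comparison.
#'
#' @param traces list of >= 2 [path_trace()]s over the same slice set.
#' @return A list: `per_slice` (data frame model/slice/distance_mm),
#'   `per_model` (data frame model/mean_distance_mm), `groups` (named list
#'   of per-model distance vectors, ready for [one_way_anova()]).
#' @export
nerve_path_compare <- function(traces) {
  if (length(traces) < 2) stop("need at least 2 models")
  idx <- lapply(traces, `[[`, "slice_index")
  ref <- idx[[1]]
  for (i in seq_along(traces)[-1]) {
    if (!identical(idx[[i]], ref)) {
      miss <- union(setdiff(ref, idx[[i]]), setdiff(idx[[i]], ref))
      stop("mismatched slice sets between models: slices ",
           paste(miss, collapse = ", "))
    }
  }
  ids <- vapply(traces, function(t) as.character(t$model_id), "")
  cen <- lapply(traces, `[[`, "centroids")
  ns <- length(ref)
  mean_cen <- Reduce(`+`, cen) / length(cen)
  per_slice <- do.call(rbind, lapply(seq_along(traces), function(m) {
    d <- sqrt(rowSums((cen[[m]] - mean_cen)^2))
    data.frame(model = ids[m], slice = ref, distance_mm = d)
  }))
  per_model <- aggregate(distance_mm ~ model, per_slice, mean)
  names(per_model)[2] <- "mean_distance_mm"
  groups <- split(per_slice$distance_mm, per_slice$model)
  list(per_slice = per_slice, per_model = per_model, groups = groups)
}
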
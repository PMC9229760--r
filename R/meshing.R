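#' Triangle surface meshes
#'
#' A mesh is a list with `vertices` (n x 3 numeric, world mm), `faces`
#' (m x 3 integer, 1-based vertex indices) and an optional per-vertex
#' `scalar` channel used for deviation heatmaps.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param scalar optional numeric per-vertex channel.
#' @return An object of class `segqa_mesh`.
#' @export
mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(scalar) && length(scalar) != nrow(vertices))
    stop("scalar channel must have one value per vertex")
  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "segqa_mesh")
}

#' @export
print.segqa_mesh <- function(x, ...) {
  dg <- mesh_diagnostics(x)
  cat(sprintf(
    "<segqa_mesh> %d vertices, %d faces, %d component(s), %swatertight\n",
    dg$n_vertices, dg$n_faces, dg$n_components,
    if (dg$watertight) "" else "NOT "))
  invisible(x)
}

#' Extract an iso-surface mesh from a binary mask
#'
#' Wraps the mask in a triangle surface: the binary field is padded with one
#' background layer (so surfaces close at grid borders) and contoured at the
#' given iso-level on a conforming tetrahedral decomposition of the voxel
#' lattice.  Vertices are placed on lattice edges in world mm; the output is
#' watertight and consistently oriented (outward normals) for any non-empty
#' input.
#'
#' @param mask a [binary_mask()].
#' @param iso iso-level on the 0/1 indicator field; default 0.5.
#' @return A [mesh()].
#' @export
extract_surface <- function(mask, iso = 0.5) {
  stopifnot(inherits(mask, "segqa_mask"))
  if (!any(mask$data))
    stop("nothing to mesh: the mask is empty")
  d <- dim(mask$data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  res <- .march_tets_cpp(as.vector(padded), d + 2L, iso,
                         mask$spacing, mask$origin - mask$spacing)
  mesh(res$vertices, res$faces)
}

#' Mesh diagnostics
#'
#' Reports closedness and topology: a mesh is watertight iff every edge is
#' shared by exactly two faces.  Never throws.
#'
#' @param x a [mesh()].
#' @return A list: `watertight`, `n_components`, `n_vertices`, `n_faces`,
#'   `euler_characteristic` (V - E + F), `bbox` (2 x 3 matrix).
#' @export
mesh_diagnostics <- function(x) {
  stopifnot(inherits(x, "segqa_mesh"))
  nv <- nrow(x$vertices)
  nf <- nrow(x$faces)
  if (nf == 0)
    return(list(watertight = FALSE, n_components = 0L, n_vertices = nv,
                n_faces = 0L, euler_characteristic = nv,
                bbox = apply(x$vertices, 2, range)))
  e <- rbind(x$faces[, 1:2], x$faces[, 2:3], x$faces[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ek)
  ne <- length(tab)
  watertight <- all(tab == 2)
  # connected components over the vertex graph (union-find)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(e))) {
    a <- find(e[r, 1]); b <- find(e[r, 2])
    if (a != b) parent[a] <- b
  }
  used <- unique(as.vector(x$faces))
  roots <- unique(vapply(used, find, 0L))
  list(watertight = watertight,
       n_components = length(roots),
       n_vertices = nv, n_faces = nf,
       euler_characteristic = nv - ne + nf,
       bbox = apply(x$vertices, 2, range))
}

#' Read and write STL surface files
#'
#' Binary STL (80-byte header, uint32 triangle count, 50-byte records) and
#' ASCII STL (solid/facet grammar) in mm, the unit convention of the rest of
#' the package (STL itself carries no units).  STL stores a triangle soup;
#' on read, vertices closer than `tol` are merged to rebuild connectivity
#' and degenerate faces are dropped.
#'
#' @param x a [mesh()].
#' @param path file path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @param tol vertex-merge tolerance on read, mm.
#' @return `read_stl` returns a [mesh()]; `write_stl` returns `path`
#'   invisibly.
#' @export
write_stl <- function(x, path, format = c("binary", "ascii")) {
  stopifnot(inherits(x, "segqa_mesh"))
  format <- match.arg(format)
  nf <- nrow(x$faces)
  if (nf == 0) stop("refusing to write an empty mesh")
  v1 <- x$vertices[x$faces[, 1], , drop = FALSE]
  v2 <- x$vertices[x$faces[, 2], , drop = FALSE]
  v3 <- x$vertices[x$faces[, 3], , drop = FALSE]
  nrm <- cross3(v2 - v1, v3 - v1)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    floats <- as.numeric(t(cbind(nrm, v1, v2, v3)))  # 12 per record
    fraw <- writeBin(floats, raw(), size = 4, endian = "little")
    rec <- matrix(as.raw(0), nrow = 50, ncol = nf)
    rec[1:48, ] <- matrix(fraw, nrow = 48)
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid segqa", con)
    block <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(block, con)
    writeLines("endsolid segqa", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path, tol = 1e-6) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = min(size, 512))
  close(con)
  # ASCII STL starts with the 'solid' keyword and contains text only;
  # anything else is treated as binary (where the count field must match)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    (grepl("facet", head_txt, useBytes = TRUE) ||
       grepl("endsolid", head_txt, useBytes = TRUE)) &&
    !any(head_raw == as.raw(0))
  if (!is_ascii) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (is.na(count) || size != 84 + 50 * as.numeric(count))
      stop("binary STL corrupt: header count ", count,
           " does not match the records present")
    body <- readBin(con, "raw", n = 50 * count)
    rec <- matrix(body, nrow = 50)
    floats <- readBin(as.vector(rec[1:48, ]), "double", n = 12 * count,
                      size = 4, endian = "little")
    tri <- matrix(floats, ncol = 12, byrow = TRUE)
    soup <- matrix(0, nrow = 3 * count, ncol = 3)
    soup[seq(1, 3 * count, by = 3), ] <- tri[, 4:6, drop = FALSE]
    soup[seq(2, 3 * count, by = 3), ] <- tri[, 7:9, drop = FALSE]
    soup[seq(3, 3 * count, by = 3), ] <- tri[, 10:12, drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    first <- trimws(lines[1])
    if (!startsWith(first, "solid"))
      stop("malformed STL at line 1: expected 'solid'")
    vx <- grepl("^\\s*vertex\\s", lines)
    kw <- trimws(lines)
    allowed <- startsWith(kw, "solid") | startsWith(kw, "facet") |
      startsWith(kw, "outer loop") | startsWith(kw, "endloop") |
      startsWith(kw, "endfacet") | startsWith(kw, "endsolid") |
      startsWith(kw, "vertex") | kw == ""
    if (any(!allowed))
      stop("malformed ASCII STL keyword at line ", which(!allowed)[1], ": '",
           kw[which(!allowed)[1]], "'")
    vals <- lapply(strsplit(trimws(lines[vx]), "\\s+"), function(tok) {
      as.numeric(tok[2:4])
    })
    soup <- do.call(rbind, vals)
    if (is.null(soup) || nrow(soup) %% 3 != 0)
      stop("malformed ASCII STL: vertex count ", NROW(soup),
           " is not a multiple of 3")
    count <- nrow(soup) / 3
  }
  # merge duplicate vertices within tol
  key <- paste(round(soup[, 1] / tol), round(soup[, 2] / tol),
               round(soup[, 3] / tol))
  uid <- match(key, unique(key))
  verts <- soup[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  mesh(verts, faces[!degen, , drop = FALSE])
}

#' Export a mesh with a per-vertex scalar channel as ASCII PLY
#'
#' STL cannot carry per-vertex scalars, so deviation heatmaps are exported
#' as PLY with a `quality` property.
#'
#' @param x a [mesh()]; its `scalar` channel (or `scalar` argument) is
#'   written as the `quality` property.
#' @param path file path.
#' @param scalar optional numeric per-vertex values overriding `x$scalar`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path, scalar = NULL) {
  stopifnot(inherits(x, "segqa_mesh"))
  s <- scalar %||% x$scalar %||% rep(0, nrow(x$vertices))
  if (length(s) != nrow(x$vertices))
    stop("scalar channel must have one value per vertex")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(x$vertices)),
               "property float x", "property float y", "property float z",
               "property float quality",
               sprintf("element face %d", nrow(x$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %.9g", x$vertices[, 1], x$vertices[, 2],
                     x$vertices[, 3], s), con)
  writeLines(sprintf("3 %d %d %d", x$faces[, 1] - 1L, x$faces[, 2] - 1L,
                     x$faces[, 3] - 1L), con)
  invisible(path)
}

#' Icosphere test mesh
#'
#' A geodesic sphere built by recursive 4-way subdivision of an icosahedron
#' with vertices projected onto the sphere — the standard analytic fixture
#' for volume/area oracles and smoothing experiments.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of subdivision rounds (0 = icosahedron;
#'   faces = 20 * 4^subdivisions).
#' @param center sphere center, mm.
#' @return A watertight, outward-oriented [mesh()].
#' @examples
#' mesh_volume(icosphere(1, 4))  # close to 4*pi/3
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_id <- new.env()
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1]] <<- p
      id <- nv + length(newV)
      edge_id[[key]] <- id
      id
    }
    newF <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  mesh(sweep(V * radius, 2, center, "+"), F)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
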
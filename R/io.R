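#' Read and write volumes and masks as NRRD or NIfTI
#'
#' Minimal raw-encoding NRRD support sufficient for scalar volumes and
#' masks: `type` double/float/short/int/uchar, `encoding raw`, little-endian,
#' with `space directions` restricted to axis-aligned (diagonal) grids, which
#' is the only geometry the package produces.  NIfTI files go through the
#' RNifti package; spacing maps to `pixdim` and the origin to the qform
#' translation.
#'
#' @param x a [image_volume()] or [binary_mask()].
#' @param path file path. NRRD: `.nrrd`; NIfTI: `.nii` / `.nii.gz`.
#' @param type NRRD sample type to write, one of `"double"`, `"float"`,
#'   `"short"`, `"uchar"`. Masks always write `uchar`.
#' @return Readers return a `segqa_volume` (or `segqa_mask` when
#'   `as_mask = TRUE`); writers return `path` invisibly.
#' @name volume_io
NULL

nrrd_types <- list(
  double = list(what = "double", size = 8),
  float  = list(what = "double", size = 4),
  short  = list(what = "integer", size = 2),
  int    = list(what = "integer", size = 4),
  uchar  = list(what = "integer", size = 1)
)

#' @rdname volume_io
#' @export
write_nrrd <- function(x, path, type = c("double", "float", "short", "uchar")) {
  type <- match.arg(type)
  is_mask <- inherits(x, "segqa_mask")
  if (is_mask) type <- "uchar"
  d <- dim(x$data)
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    paste0("type: ", if (type == "uchar") "unsigned char" else type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            x$origin[1], x$origin[2], x$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  tt <- nrrd_types[[type]]
  vals <- if (tt$what == "integer") as.integer(x$data) else as.numeric(x$data)
  writeBin(vals, con, size = tt$size, endian = "little")
  invisible(path)
}

parse_nrrd_vectors <- function(value) {
  m <- gregexpr("\\(([^)]*)\\)", value)[[1]]
  parts <- regmatches(value, gregexpr("\\(([^)]*)\\)", value))[[1]]
  lapply(parts, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

#' @rdname volume_io
#' @param as_mask logical: return a `segqa_mask` (data coerced to logical).
#' @export
read_nrrd <- function(path, as_mask = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3)
      fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  enc <- fields[["encoding"]]
  if (is.null(enc) || enc != "raw")
    stop("unsupported NRRD encoding: ", enc %||% "<missing>",
         " (only 'raw' is supported)")
  if (!is.null(fields[["dimension"]]) && fields[["dimension"]] != "3")
    stop("only 3-D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type_raw <- fields[["type"]]
  type <- switch(type_raw,
    "double" = "double", "float" = "float",
    "short" = "short", "signed short" = "short", "int" = "int",
    "unsigned char" = "uchar", "uchar" = "uchar", "uint8" = "uchar",
    stop("unsupported NRRD type: ", type_raw))
  endian <- fields[["endian"]] %||% "little"
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    for (i in 1:3) {
      v <- dirs[[i]]
      if (sum(v != 0) != 1 || v[i] == 0)
        stop("only axis-aligned NRRD space directions are supported")
      spacing[i] <- v[i]
    }
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  tt <- nrrd_types[[type]]
  n <- prod(sizes)
  vals <- readBin(con, tt$what, n = n, size = tt$size, endian = endian,
                  signed = !(type == "uchar"))
  if (length(vals) < n)
    stop("NRRD data block truncated: expected ", n, " samples, got ",
         length(vals))
  arr <- array(as.numeric(vals), dim = sizes)
  if (as_mask)
    binary_mask(arr != 0, spacing, origin)
  else
    image_volume(arr, spacing, origin)
}

#' @rdname volume_io
#' @export
write_nifti_volume <- function(x, path) {
  img <- RNifti::asNifti(if (is.logical(x$data)) x$data + 0 else x$data)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(c(x$spacing, 1))
  m[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_nifti_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  if (as_mask)
    binary_mask(arr != 0, spacing, origin)
  else
    image_volume(arr, spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
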
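#' @title MetaImage (.mhd/.raw) volumes
#' @description
#' Minimal reader/writer for the MetaImage format used by LUNA16-style
#' CT archives: a plain-text `.mhd` header (key = value lines) plus a
#' `.raw` voxel payload.  Voxels are stored with x varying fastest; the
#' in-memory convention is an `[x, y, z]` array (matching R's
#' column-major layout), with `origin` and `spacing` as (x, y, z)
#' millimetre triples.  Supported element types: MET_SHORT (the usual
#' Hounsfield storage), MET_UCHAR, MET_FLOAT and MET_DOUBLE,
#' little-endian.
#' @name metaimage
NULL

#' Construct a CT volume record
#'
#' @param voxels 3-D array of Hounsfield units, `[x, y, z]`.
#' @param origin world-frame offset of voxel (0,0,0), mm (x, y, z).
#' @param spacing voxel pitch, mm (x, y, z); strictly positive.
#' @param series_id identifier string.
#' @return An object of class `volume_record`.
#' @export
volume_record <- function(voxels, origin, spacing, series_id = "volume") {
  stopifnot(length(dim(voxels)) == 3L, length(origin) == 3L,
            length(spacing) == 3L)
  if (any(spacing <= 0))
    stop("format error: ElementSpacing must be strictly positive",
         call. = FALSE)
  if (length(voxels) == 0L)
    stop("format error: empty voxel array", call. = FALSE)
  structure(list(voxels = voxels, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 series_id = as.character(series_id)),
            class = "volume_record")
}

#' @export
print.volume_record <- function(x, ...) {
  cat("CT volume ", x$series_id, ": ",
      paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(x$spacing, collapse = ", "),
      ") mm, origin (", paste(x$origin, collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

.met_types <- list(
  MET_SHORT  = list(size = 2L, what = "integer", signed = TRUE),
  MET_USHORT = list(size = 2L, what = "integer", signed = FALSE),
  MET_UCHAR  = list(size = 1L, what = "integer", signed = FALSE),
  MET_CHAR   = list(size = 1L, what = "integer", signed = TRUE),
  MET_FLOAT  = list(size = 4L, what = "numeric", signed = TRUE),
  MET_DOUBLE = list(size = 8L, what = "numeric", signed = TRUE))

#' Read a MetaImage volume
#'
#' @param header_path path to the `.mhd` header; the voxel payload is
#'   located via its `ElementDataFile` field (resolved relative to the
#'   header's directory).
#' @return A [volume_record()]; the series id is the header file name
#'   without extension.
#' @export
read_metaimage <- function(header_path) {
  if (!file.exists(header_path))
    stop("format error: header not found: ", header_path, call. = FALSE)
  lines <- readLines(header_path, warn = FALSE)
  kv <- strsplit(lines[nzchar(trimws(lines))], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  h <- stats::setNames(as.list(vals), keys)
  need <- function(field) {
    if (is.null(h[[field]]))
      stop("format error: missing header field ", field, call. = FALSE)
    h[[field]]
  }
  nums <- function(field) as.numeric(strsplit(need(field), "\\s+")[[1]])
  if (as.integer(need("NDims")) != 3L)
    stop("format error: NDims must be 3", call. = FALSE)
  dims <- as.integer(nums("DimSize"))
  spacing <- if (!is.null(h$ElementSpacing)) nums("ElementSpacing")
             else nums("ElementSize")
  origin <- if (!is.null(h$Offset)) nums("Offset")
            else if (!is.null(h$Origin)) nums("Origin") else c(0, 0, 0)
  type <- .met_types[[need("ElementType")]]
  if (is.null(type))
    stop("format error: unsupported ElementType ", h$ElementType,
         call. = FALSE)
  msb <- isTRUE(toupper(c(h$ElementByteOrderMSB,
                          h$BinaryDataByteOrderMSB)[1]) == "TRUE")
  raw_path <- file.path(dirname(header_path), need("ElementDataFile"))
  if (!file.exists(raw_path))
    stop("format error: ElementDataFile not found: ", raw_path,
         call. = FALSE)
  n <- prod(dims)
  expected <- n * type$size
  if (file.size(raw_path) < expected)
    stop("format error: DimSize declares ", n, " voxels (",
         expected, " bytes) but ", basename(raw_path), " holds only ",
         file.size(raw_path), " bytes", call. = FALSE)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vox <- readBin(con, what = type$what, n = n, size = type$size,
                 signed = type$signed,
                 endian = if (msb) "big" else "little")
  volume_record(array(as.numeric(vox), dims), origin, spacing,
                series_id = tools::file_path_sans_ext(basename(header_path)))
}

#' Write a volume as MetaImage
#'
#' @param volume a [volume_record()].
#' @param header_path output `.mhd` path; the payload is written next to
#'   it with the same stem and a `.raw` extension.
#' @param element_type storage type (default MET_SHORT; values are
#'   rounded).
#' @return `header_path`, invisibly.
#' @export
write_metaimage <- function(volume, header_path,
                            element_type = "MET_SHORT") {
  stopifnot(inherits(volume, "volume_record"))
  type <- .met_types[[element_type]]
  if (is.null(type))
    stop("format error: unsupported ElementType ", element_type,
         call. = FALSE)
  raw_name <- paste0(tools::file_path_sans_ext(basename(header_path)),
                     ".raw")
  dims <- dim(volume$voxels)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
           paste("Offset =", paste(volume$origin, collapse = " ")),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, header_path)
  con <- file(file.path(dirname(header_path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(volume$voxels)
  if (type$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = type$size, endian = "little")
  invisible(header_path)
}
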
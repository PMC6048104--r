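# Volume containers and medical-image I/O (NIfTI-1, MetaImage).
#
# Canonical in-memory convention: a 3D array indexed [x, y, z] with x the
# fastest-varying axis (R's native column-major order), 0-based voxel p maps
# to physical position origin + p * spacing. Volumes are assumed axis-aligned;
# a non-diagonal orientation matrix in a NIfTI header triggers a warning and
# is otherwise ignored.

#' Construct a scalar volume
#'
#' A `volume` holds a 3D numeric array of intensities together with its voxel
#' spacing (mm) and physical origin (mm). Intensities are stored as doubles
#' regardless of the on-disk type so downstream covariance arithmetic is
#' stable.
#'
#' @param data 3D numeric array, `[x, y, z]`, finite everywhere.
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param origin numeric length-3 physical offset in mm.
#' @return An object of class `volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume data contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite numbers")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume")
}

#' Construct an integer label volume
#'
#' Shares the geometry convention of [volume()]; voxel values are
#' non-negative integers (0 = background, 1 = organ for binary masks).
#'
#' @param data 3D array of non-negative integers.
#' @inheritParams volume
#' @return An object of class `c("label_volume", "volume")` with an extra
#'   `label_set` field (sorted distinct labels present).
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label data must be a 3D array")
  if (!all(is.finite(data)))
    stop("label data contains non-finite values")
  if (any(data != round(data)) || any(data < 0))
    stop("labels must be non-negative integers")
  v <- volume(data, spacing, origin)
  v$data <- array(as.double(round(v$data)), dim = dim(v$data))
  v$label_set <- sort(unique(as.vector(v$data)))
  class(v) <- c("label_volume", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  if (!is.null(x$label_set))
    cat("  labels:", paste(x$label_set, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a volume to a label volume
#'
#' @param v a [volume()] whose data are non-negative integers.
#' @return A [label_volume()] on the same grid.
#' @export
as_label_volume <- function(v) {
  stopifnot(inherits(v, "volume"))
  label_volume(v$data, v$spacing, v$origin)
}

#' Test whether two volumes share a grid
#'
#' True iff shapes are identical and spacings agree within `1e-6` relative
#' tolerance. Origins are not compared: pre-warped inputs occasionally carry
#' sloppy offsets, and every algorithm here works in voxel/physical-offset
#' space.
#'
#' @param a,b [volume()] or [label_volume()] objects.
#' @return logical scalar.
#' @export
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "volume"), inherits(b, "volume"))
  if (!identical(dim(a$data), dim(b$data))) return(FALSE)
  all(abs(a$spacing - b$spacing) <= 1e-6 * pmax(a$spacing, b$spacing))
}

assert_same_grid <- function(a, b, what = "input") {
  if (!check_same_grid(a, b))
    stop(sprintf("%s is not on the same grid as the target", what))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# NIfTI-1

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop("cannot read NIfTI header from '", path, "'")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L)
      stop("'", path, "' is not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("'", path, "' is not a NIfTI-1 file (bad magic)")
  rb <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dim_field <- rb(40, "integer", 8L, 2L)
  ndim <- dim_field[1]
  dims <- dim_field[-1]
  extra <- if (ndim > 3L) dims[4:ndim] else integer(0)
  if (ndim < 3L || any(extra != 1L))
    stop("'", path, "' is not a 3D image (ndim = ", ndim, ")")
  shape <- dims[1:3]
  datatype <- rb(70, "integer", 1L, 2L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, " in '", path, "'")
  pixdim <- rb(76, "double", 8L, 4L)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in NIfTI header of '", path, "'")
  vox_offset <- rb(108, "double", 1L, 4L)
  scl_slope <- rb(112, "double", 1L, 4L)
  scl_inter <- rb(116, "double", 1L, 4L)
  sform_code <- rb(254, "integer", 1L, 2L)
  origin <- rb(268, "double", 3L, 4L)
  if (sform_code > 0L) {
    srow <- matrix(rb(280, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
    origin <- srow[, 4]
    rot <- srow[, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
      warning("'", path, "' has a non-axis-aligned orientation matrix; ",
              "treating the volume as axis-aligned")
  }
  nskip <- as.integer(round(vox_offset)) - 348L
  if (nskip > 0L) readBin(con, "raw", n = nskip)
  nvox <- prod(shape)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NIfTI data in '", path, "'")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (any(!is.finite(vals)))
    stop("'", path, "' contains non-finite voxel values")
  volume(array(vals, dim = shape), spacing, origin)
}

write_nifti <- function(v, path) {
  is_label <- inherits(v, "label_volume")
  datatype <- if (is_label) 8L else 16L         # int32 / float32
  bitpix <- if (is_label) 32L else 32L
  dm <- dim(v$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # unused through dim_info
  wb(as.integer(c(3L, dm, 1L, 1L, 1L, 1L)), 2L)  # dim
  wb(c(0, 0, 0), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(datatype, 2L)
  wb(bitpix, 2L)
  wb(0L, 2L)                                     # slice_start
  wb(c(1, v$spacing, 1, 1, 1, 1), 4L)            # pixdim
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  writeBin(raw(3L), con)                         # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units: mm
  wb(c(0, 0, 0), 4L)                             # cal_max/min, slice_duration
  wb(0, 4L)                                      # toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(80L + 24L), con)                  # descrip, aux_file
  wb(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  wb(c(0, 0, 0), 4L)                             # quatern b c d
  wb(v$origin, 4L)                               # qoffset
  wb(c(v$spacing[1], 0, 0, v$origin[1]), 4L)     # srow_x
  wb(c(0, v$spacing[2], 0, v$origin[2]), 4L)     # srow_y
  wb(c(0, 0, v$spacing[3], v$origin[3]), 4L)     # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension indicator
  if (is_label) {
    writeBin(as.integer(v$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(v$data), con, size = 4L, endian = "little")
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# MetaImage (.mhd + .raw, or single-file .mha)

meta_types <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_SHORT = "int16",
                MET_USHORT = "uint16", MET_INT = "int32", MET_UINT = "uint32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

meta_read_spec <- function(mt) {
  switch(mt,
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
    MET_FLOAT  = list(what = "double", size = 4L, signed = TRUE),
    MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE),
    stop("unsupported MetaImage ElementType '", mt, "'"))
}

parse_mhd_header <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_,
                 "")
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else
                 NA_character_, "")
  stats::setNames(as.list(vals[!is.na(keys)]), keys[!is.na(keys)])
}

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  is_mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (is_mha) {
    # header is the text up to and including the ElementDataFile line
    m <- grepRaw("ElementDataFile", raw_all, fixed = TRUE)
    if (length(m) == 0L) stop("no ElementDataFile key in '", path, "'")
    nl <- grepRaw("\n", raw_all, offset = m[1], fixed = TRUE)
    if (length(nl) == 0L) stop("malformed MetaImage header in '", path, "'")
    hdr_end <- nl[1]
    hdr <- parse_mhd_header(strsplit(rawToChar(raw_all[seq_len(hdr_end)]),
                                     "\n")[[1]])
    data_raw <- raw_all[(hdr_end + 1L):length(raw_all)]
  } else {
    hdr <- parse_mhd_header(readLines(path, warn = FALSE))
    df <- hdr$ElementDataFile
    if (is.null(df)) stop("no ElementDataFile key in '", path, "'")
    dfp <- file.path(dirname(path), df)
    if (!file.exists(dfp)) stop("MetaImage data file '", dfp, "' not found")
    data_raw <- readBin(dfp, "raw", n = file.size(dfp))
  }
  if (!is.null(hdr$CompressedData) &&
      toupper(hdr$CompressedData) == "TRUE")
    data_raw <- memDecompress(data_raw, type = "gzip")
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L) stop("'", path, "' is not a 3D image (NDims = ",
                        ndims, ")")
  shape <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||%
                                   hdr$ElementSize %||% "1 1 1",
                                 "\\s+")[[1]])
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in MetaImage header of '", path, "'")
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                "\\s+")[[1]])
  msb <- toupper(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||%
                   "FALSE") == "TRUE"
  spec <- meta_read_spec(hdr$ElementType %||% "MET_FLOAT")
  nvox <- prod(shape)
  vals <- readBin(data_raw, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed,
                  endian = if (msb) "big" else "little")
  if (length(vals) < nvox) stop("truncated MetaImage data in '", path, "'")
  if (any(!is.finite(vals)))
    stop("'", path, "' contains non-finite voxel values")
  volume(array(as.double(vals), dim = shape), spacing, origin)
}

write_metaimage <- function(v, path) {
  is_label <- inherits(v, "label_volume")
  is_mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  etype <- if (is_label) "MET_INT" else "MET_FLOAT"
  dm <- dim(v$data)
  datafile <- if (is_mha) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dm, collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(v$spacing, digits = 17), collapse = " ")),
           paste("Offset =",
                 paste(format(v$origin, digits = 17), collapse = " ")),
           paste("ElementType =", etype),
           paste("ElementDataFile =", datafile))
  write_payload <- function(con) {
    if (is_label)
      writeBin(as.integer(v$data), con, size = 4L, endian = "little")
    else
      writeBin(as.double(v$data), con, size = 4L, endian = "little")
  }
  if (is_mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    write_payload(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    write_payload(con)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Read a 3D volume from NIfTI-1 or MetaImage
#'
#' Format is chosen from the file extension: `.nii` / `.nii.gz` for NIfTI-1,
#' `.mhd` / `.mha` for MetaImage. The returned array uses the package-wide
#' `[x, y, z]` axis order with x fastest. Non-3D images, non-positive
#' spacings and non-finite voxel values are rejected.
#'
#' @param path path to an existing image file.
#' @return A [volume()].
#' @seealso [write_volume()], [read_label_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    read_nifti(path)
  else if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
    read_metaimage(path)
  else stop("unrecognized image extension for '", path,
            "' (expected .nii[.gz], .mhd or .mha)")
}

#' Read an integer label volume
#'
#' [read_volume()] followed by integer validation; values must already be
#' non-negative integers (within float rounding of the on-disk type).
#'
#' @inheritParams read_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  v <- read_volume(path)
  if (max(abs(v$data - round(v$data))) > 1e-6)
    stop("'", path, "' does not contain integer labels")
  label_volume(round(v$data), v$spacing, v$origin)
}

#' Write a volume or label volume
#'
#' Label volumes are stored as 32-bit integers (bit-exact round trip);
#' intensity volumes as 32-bit floats (round trip within float32 rounding).
#' Geometry (spacing, origin) is preserved exactly in MetaImage and to
#' float32 precision in NIfTI-1.
#'
#' @param v a [volume()] or [label_volume()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    write_nifti(v, path)
  else if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
    write_metaimage(v, path)
  else stop("unrecognized image extension for '", path, "'")
}
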
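# File axis convention for NIfTI and MetaImage: file x = image column,
# file y = image row, file z = slice, so on-disk spacing is
# (col_mm, row_mm, slice_mm) while the in-memory order is (slice, row, col).

.vol_to_file_array <- function(voxels) aperm(voxels, c(3, 2, 1))
.file_array_to_vol <- function(a) aperm(a, c(3, 2, 1))

#' Read a 3-D volume from NIfTI or MetaImage
#'
#' @param path path to a `.nii`/`.nii.gz` (NIfTI-1) or `.mha`/`.mhd`
#'   (MetaImage) file holding a 3-D image with spacing metadata.
#' @return A [ct_volume] with axes normalized to `(slice, row, col)`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    return(.read_metaimage(path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume; file has shape ",
         paste(dim(a), collapse = "x"))
  pd <- RNifti::pixdim(img)
  ct_volume(.file_array_to_vol(a), spacing = pd[c(2, 1, 3)],
            meta = list(source = path, format = "nifti"))
}

#' Write a volume or mask to NIfTI-1
#'
#' `write_volume()` stores attenuation values as 64-bit floats;
#' `write_mask()` stores strictly binary masks (and small label volumes, codes
#' 0 = background, 1 = SAT, 2 = VAT, 3 = removed bone fat) as unsigned 8-bit.
#' Uncompressed `.nii` output is byte-reproducible across runs; `.nii.gz`
#' also works but embeds a gzip timestamp.
#'
#' @param volume a [ct_volume].
#' @param mask logical (or 0/1 numeric) 3-D array; for `write_labels`, an
#'   integer array with values 0..255.
#' @param spacing voxel spacing `(row_mm, col_mm, slice_mm)`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  a <- .vol_to_file_array(volume$voxels)
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- volume$spacing[c(2, 1, 3)]
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, spacing, path) {
  mask <- as_mask(mask)
  write_labels(array(as.integer(mask), dim = dim(mask)), spacing, path)
}

#' @rdname write_volume
#' @export
write_labels <- function(mask, spacing, path) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("labels must form a 3-D array")
  if (any(mask < 0 | mask > 255 | mask != round(mask)))
    stop("label codes must be integers in 0..255")
  a <- .vol_to_file_array(array(as.integer(mask), dim = dim(mask)))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- as.numeric(spacing)[c(2, 1, 3)]
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a label or mask volume
#'
#' @param path a NIfTI/MetaImage file written by [write_mask()] or
#'   [write_labels()].
#' @return Integer 3-D array `(slice, row, col)` with a `spacing` attribute.
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  out <- array(as.integer(round(v$voxels)), dim = dim(v$voxels))
  attr(out, "spacing") <- v$spacing
  out
}

# ---- MetaImage (uncompressed) ----------------------------------------------

.mha_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- character(0)
    repeat {  # read one header line byte-wise so binary data is untouched
      ch <- readBin(con, "raw", 1)
      if (!length(ch) || ch == as.raw(10)) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    if (!nzchar(trimws(line))) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop("expected a 3-D MetaImage; NDims = ", ndims)
  if (tolower(hdr$CompressedData %||% "false") == "true")
    stop("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "",
                            "\\s+")[[1]])
  if (length(sp) != 3L || any(!is.finite(sp)))
    stop("MetaImage file lacks usable ElementSpacing metadata")
  tinfo <- .mha_types[[hdr$ElementType %||% ""]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", hdr$ElementType)
  msb <- tolower(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||%
                   "false") == "true"
  n <- prod(dims)
  if (hdr$ElementDataFile != "LOCAL") {
    close(con); on.exit()
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    con <- file(raw_path, "rb")
    on.exit(close(con))
  }
  v <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
               signed = tinfo$signed, endian = if (msb) "big" else "little")
  if (length(v) != n) stop("MetaImage pixel data truncated")
  a <- array(as.double(v), dim = dims)   # dims are (x, y, z) = (col, row, slice)
  ct_volume(.file_array_to_vol(a), spacing = sp[c(2, 1, 3)],
            meta = list(source = path, format = "metaimage"))
}

# internal writer (uncompressed .mha, LOCAL data), used by tests and the
# phantom CLI; MET_DOUBLE keeps HU exact
.write_mha <- function(volume, path, type = "MET_DOUBLE") {
  stopifnot(inherits(volume, "ct_volume"))
  tinfo <- .mha_types[[type]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", type)
  a <- .vol_to_file_array(volume$voxels)
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "DimSize = ", paste(dim(a), collapse = " "), "\n",
    "ElementSpacing = ", paste(volume$spacing[c(2, 1, 3)], collapse = " "), "\n",
    "ElementType = ", type, "\n",
    "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  v <- as.vector(a)
  if (tinfo$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = tinfo$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
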
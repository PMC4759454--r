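# Minimal single-frame CT DICOM support, written for this package because the
# environment ships no R DICOM reader.  Scope: little-endian explicit- and
# implicit-VR transfer syntaxes, uncompressed 16-bit pixel data, defined
# element lengths.  That covers what CT scanners emit for axial series and
# what the companion writer produces.

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.ts_implicit_le <- "1.2.840.10008.1.2"
.uid_root <- "1.2.826.0.1.3680043.9.7484"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# VRs for the tags the reader interprets (needed under implicit VR)
.dicom_dict <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0018,0050" = "DS", "0018,0088" = "DS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "7FE0,0010" = "OW"
)

.u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
.u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

# parse a contiguous run of data elements; returns named list of raw values
.parse_elements <- function(raw, off, end, explicit, stop_after_pixeldata = TRUE) {
  out <- list()
  while (off + 8 <= end) {
    group <- .u16(raw, off); element <- .u16(raw, off + 2)
    if (explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% .long_vrs) {
        len <- .u32(raw, off + 8); voff <- off + 12
      } else {
        len <- .u16(raw, off + 6); voff <- off + 8
      }
    } else {
      vr <- unname(.dicom_dict[.tag_key(group, element)])
      len <- .u32(raw, off + 4); voff <- off + 8
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements (sequences) are not supported")
    if (voff + len > end) stop("truncated DICOM element at byte ", off)
    key <- .tag_key(group, element)
    out[[key]] <- raw[seq_len(len) + voff]
    attr(out[[key]], "vr") <- vr
    off <- voff + len
    if (stop_after_pixeldata && key == "7FE0,0010") break
  }
  attr(out, "end_offset") <- off
  out
}

.dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  pad <- c(as.raw(0L), as.raw(32L))  # trailing NUL / space padding
  while (length(el) && el[length(el)] %in% pad) el <- el[-length(el)]
  rawToChar(el)
}
.dcm_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.dcm_string(el), "\\\\")[[1]])
}
.dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el, "integer", n = length(el) %/% 2L, size = 2L,
          signed = FALSE, endian = "little")
}

# read one single-frame DICOM file into a list of interpreted fields
.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  off <- 132
  # file meta group is always explicit VR little endian
  if (.u16(raw, off) != 2L) stop("missing DICOM file meta group: ", path)
  vr <- rawToChar(raw[(off + 5):(off + 6)])
  len <- .u16(raw, off + 6)
  meta_len <- .u32(raw, off + 8)
  off <- off + 8 + len
  meta <- .parse_elements(raw, off, off + meta_len, explicit = TRUE,
                          stop_after_pixeldata = FALSE)
  ts <- .dcm_string(meta[["0002,0010"]]) %||% .ts_explicit_le
  explicit <- ts == .ts_explicit_le
  if (!explicit && ts != .ts_implicit_le)
    stop("unsupported transfer syntax ", ts, " in ", path)
  els <- .parse_elements(raw, attr(meta, "end_offset"), length(raw), explicit)

  rows <- .dcm_us(els[["0028,0010"]]); cols <- .dcm_us(els[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  bits <- .dcm_us(els[["0028,0100"]]) %||% 16L
  if (bits != 16L) stop("only 16-bit pixel data is supported (", path, ")")
  signed <- (.dcm_us(els[["0028,0103"]]) %||% 0L) == 1L
  px <- els[["7FE0,0010"]]
  if (is.null(px)) stop("missing PixelData in ", path)
  stored <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (!signed) stored <- .dcm_us(px)
  if (length(stored) != rows * cols) stop("pixel data truncated in ", path)
  slope <- (.dcm_numeric(els[["0028,1053"]]) %||% 1)[1]
  intercept <- (.dcm_numeric(els[["0028,1052"]]) %||% 0)[1]
  list(
    series_uid = .dcm_string(els[["0020,000E"]]),
    instance = as.integer(.dcm_numeric(els[["0020,0013"]]) %||% NA),
    position = .dcm_numeric(els[["0020,0032"]]),
    pixel_spacing = .dcm_numeric(els[["0028,0030"]]),   # (row_mm, col_mm)
    slice_thickness = (.dcm_numeric(els[["0018,0050"]]) %||% NA_real_)[1],
    spacing_between = (.dcm_numeric(els[["0018,0088"]]) %||% NA_real_)[1],
    hu = t(matrix(slope * stored + intercept, cols, rows))
  )
}

#' Read an axial CT DICOM series
#'
#' Reads every DICOM file in a directory, checks that they belong to one
#' series, sorts the slices by physical position (slice-normal coordinate of
#' Image Position Patient; falling back to Instance Number when positions are
#' absent), and converts stored values to Hounsfield units via the rescale
#' slope and intercept.  Supported encodings: little-endian explicit or
#' implicit VR, uncompressed 16-bit single-frame images.
#'
#' @param directory_path directory holding exactly one axial CT series.
#' @return A [ct_volume].
#' @export
read_ct_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in ", directory_path)
  slices <- lapply(files, .read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", character(1)))
  if (length(uids) != 1L)
    stop("directory contains ", length(uids), " different series UIDs; ",
         "expected one series")
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps) || length(ps) != 2L || any(!is.finite(ps)))
    stop("missing PixelSpacing metadata in series")

  z <- vapply(slices, function(s)
    if (!is.null(s$position) && length(s$position) >= 3) s$position[3]
    else NA_real_, numeric(1))
  if (all(is.finite(z))) {
    ord <- order(z)
    if (anyDuplicated(z))
      stop("non-monotonic slice positions: duplicated slice locations")
    z <- z[ord]
  } else {
    inst <- vapply(slices, function(s) as.numeric(s$instance %||% NA),
                   numeric(1))
    if (any(!is.finite(inst)))
      stop("slices carry neither positions nor instance numbers; cannot sort")
    ord <- order(inst)
    z <- NULL
  }
  slices <- slices[ord]

  if (!is.null(z) && length(z) > 1L) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-3)
      stop("non-monotonic or irregular slice positions (intervals ",
           paste(signif(range(dz), 6), collapse = " .. "), " mm)")
    slice_mm <- mean(dz)
  } else {
    slice_mm <- slices[[1]]$spacing_between
    if (!is.finite(slice_mm)) slice_mm <- slices[[1]]$slice_thickness
    if (!is.finite(slice_mm))
      stop("cannot determine the slice interval: single slice without ",
           "SpacingBetweenSlices/SliceThickness")
  }

  d2 <- dim(slices[[1]]$hu)
  vox <- array(0, dim = c(length(slices), d2[1], d2[2]))
  for (s in seq_along(slices)) {
    if (!identical(dim(slices[[s]]$hu), d2))
      stop("slice dimensions differ within the series")
    vox[s, , ] <- slices[[s]]$hu
  }
  ct_volume(vox, spacing = c(ps[1], ps[2], slice_mm),
            meta = list(source = directory_path, format = "dicom",
                        series_uid = uids))
}

# ---- writer ----------------------------------------------------------------

.dcm_el_explicit <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
  tag <- writeBin(c(group, element), raw(), size = 2L, endian = "little")
  if (vr %in% .long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

.el_str <- function(group, element, vr, s)
  .dcm_el_explicit(group, element, vr, charToRaw(s))
.el_us <- function(group, element, v)
  .dcm_el_explicit(group, element, "US",
                   writeBin(as.integer(v), raw(), size = 2L, endian = "little"))

#' Write a CT volume as a DICOM series
#'
#' Companion writer to [read_ct_series()], mainly used to exercise DICOM
#' ingestion with phantoms: one explicit-VR little-endian file per slice,
#' 16-bit unsigned stored values with rescale slope 1 and intercept -1024.
#' Attenuations must be integers in `[-1024, 64511]` HU so the round trip is
#' exact.
#'
#' @param volume a [ct_volume] with integer-valued voxels.
#' @param directory_path output directory (created if missing).
#' @param series_uid Series Instance UID; a fixed private-root UID by
#'   default.  UIDs are deterministic: no randomness, no timestamps.
#' @return The directory path, invisibly.
#' @export
write_ct_series <- function(volume, directory_path,
                            series_uid = paste0(.uid_root, ".1.1")) {
  stopifnot(inherits(volume, "ct_volume"))
  vox <- volume$voxels
  if (any(vox != round(vox)))
    stop("DICOM export stores integer HU; volume has non-integer values")
  intercept <- -1024
  stored_rng <- range(vox) - intercept
  if (stored_rng[1] < 0 || stored_rng[2] > 65535)
    stop("attenuations outside the representable range [-1024, 64511] HU")
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vox)
  sp <- volume$spacing
  ct_class <- "1.2.840.10008.5.1.4.1.1.2"
  for (s in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", s)
    meta <- c(
      .el_str(0x0002L, 0x0002L, "UI", ct_class),
      .el_str(0x0002L, 0x0003L, "UI", sop_uid),
      .el_str(0x0002L, 0x0010L, "UI", .ts_explicit_le)
    )
    meta <- c(.dcm_el_explicit(0x0002L, 0x0000L, "UL",
                               writeBin(length(meta), raw(), size = 4L,
                                        endian = "little")),
              meta)
    stored <- as.integer(as.vector(t(matrix(vox[s, , ], d[2], d[3]))) - intercept)
    px <- writeBin(stored, raw(), size = 2L, endian = "little")
    z <- (s - 1) * sp[3]
    ds <- function(x) sub("0+$", "", sub("\\.$", "", sprintf("%.6f", x)))
    body <- c(
      .el_str(0x0008L, 0x0016L, "UI", ct_class),
      .el_str(0x0008L, 0x0018L, "UI", sop_uid),
      .el_str(0x0008L, 0x0060L, "CS", "CT"),
      .el_str(0x0018L, 0x0050L, "DS", ds(sp[3])),
      .el_str(0x0018L, 0x0088L, "DS", ds(sp[3])),
      .el_str(0x0020L, 0x000DL, "UI", paste0(.uid_root, ".0.1")),
      .el_str(0x0020L, 0x000EL, "UI", series_uid),
      .el_str(0x0020L, 0x0013L, "IS", as.character(s)),
      .el_str(0x0020L, 0x0032L, "DS",
              paste(ds(0), ds(0), ds(z), sep = "\\")),
      .el_str(0x0020L, 0x0037L, "DS",
              paste(ds(c(1, 0, 0, 0, 1, 0)), collapse = "\\")),
      .el_us(0x0028L, 0x0002L, 1L),
      .el_str(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      .el_us(0x0028L, 0x0010L, d[2]),
      .el_us(0x0028L, 0x0011L, d[3]),
      .el_str(0x0028L, 0x0030L, "DS", paste(ds(sp[1]), ds(sp[2]), sep = "\\")),
      .el_us(0x0028L, 0x0100L, 16L),
      .el_us(0x0028L, 0x0101L, 16L),
      .el_us(0x0028L, 0x0102L, 15L),
      .el_us(0x0028L, 0x0103L, 0L),
      .el_str(0x0028L, 0x1052L, "DS", as.character(intercept)),
      .el_str(0x0028L, 0x1053L, "DS", "1"),
      .dcm_el_explicit(0x7FE0L, 0x0010L, "OW", px)
    )
    out <- file.path(directory_path, sprintf("slice_%04d.dcm", s))
    con <- file(out, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(directory_path)
}
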
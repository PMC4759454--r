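#' Hounsfield-unit thresholds for the pipeline
#'
#' Bundles every HU threshold the pipeline uses.  Defaults follow the standard
#' CT conventions for abdominal fat quantification: adipose tissue attenuates
#' between -190 and -30 HU, air sits at -1000 HU, and cortical bone exceeds
#' 1000 HU.
#'
#' @param fat_low lower bound of the fat attenuation band, HU (default -190).
#' @param fat_high upper bound of the fat attenuation band, HU (default -30).
#' @param air air threshold, HU (default -1000): voxels at or below it are
#'   background.
#' @param bone_seed seed threshold for bone region growing, HU (default 1000).
#' @param bone_grow acceptance threshold for bone region growing, HU
#'   (default 150), approximating the cortical/soft-tissue boundary.
#'
#' @return An object of class `ct_thresholds`.
#' @examples
#' thresholds()
#' thresholds(fat_high = -20)
#' @export
thresholds <- function(fat_low = -190, fat_high = -30, air = -1000,
                       bone_seed = 1000, bone_grow = 150) {
  th <- list(fat_low = as.numeric(fat_low), fat_high = as.numeric(fat_high),
             air = as.numeric(air), bone_seed = as.numeric(bone_seed),
             bone_grow = as.numeric(bone_grow))
  if (!(th$fat_low < th$fat_high && th$fat_high < th$bone_grow &&
        th$bone_grow <= th$bone_seed))
    stop("thresholds must satisfy fat_low < fat_high < bone_grow <= bone_seed")
  if (!(th$air <= th$fat_low))
    stop("air threshold must not exceed fat_low")
  structure(th, class = "ct_thresholds")
}

#' @export
print.ct_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<ct_thresholds> fat [%g, %g] HU, air %g HU, ",
                     "bone seed > %g HU, bone grow >= %g HU\n"),
              x$fat_low, x$fat_high, x$air, x$bone_seed, x$bone_grow))
  invisible(x)
}

#' Detect the body region of a CT volume
#'
#' Per axial slice, voxels strictly above the air threshold form the
#' foreground; a one-pixel morphological opening removes isolated noise
#' speckle (with image noise, a large fraction of air voxels fluctuates above
#' the threshold and would otherwise percolate into the body component).
#' The foreground is then labeled into 8-connected components and the
#' component with the largest pixel area is retained as the body, which
#' discards the scanner bed and sheets.  Interior holes (bowel gas, lung
#' bases) are finally filled so downstream fat thresholding operates on the
#' full anatomical cross-section.
#'
#' @param volume a [ct_volume].
#' @param thresholds a [thresholds] object.
#' @param min_area minimum pixel area for a slice's body component; slices
#'   whose largest component is smaller get an empty body mask and a warning.
#' @param fill_holes fill interior holes per slice (default `TRUE`).  The
#'   unfilled mask is what thresholding alone produces; exposed mainly for
#'   testing the monotonicity of the air threshold.
#'
#' @return A logical body mask aligned to the volume grid.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(3, 64, 64)))
#' body <- detect_body_region(ph$volume, thresholds())
#' sum(body & !ph$body_truth)  # no voxels outside the constructed body
#' @export
detect_body_region <- function(volume, thresholds = ctadipose::thresholds(),
                               min_area = 100, fill_holes = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  body <- empty_mask(d)
  empty_slices <- integer(0)
  despeckle <- EBImage::makeBrush(3, shape = "box")
  for (s in seq_len(d[1])) {
    fg <- matrix(volume$voxels[s, , ] > thresholds$air, d[2], d[3])
    if (any(fg)) fg <- EBImage::opening(fg + 0, despeckle) > 0
    if (!any(fg)) { empty_slices <- c(empty_slices, s); next }
    lab <- .cc_label2d8(fg)
    sizes <- tabulate(lab[lab > 0L])
    if (max(sizes) < min_area) { empty_slices <- c(empty_slices, s); next }
    keep <- lab == which.max(sizes)
    if (fill_holes)
      keep <- EBImage::fillHull(keep) > 0
    body[s, , ] <- keep
  }
  if (length(empty_slices) == d[1])
    stop("no body region found on any slice (is the volume all air?)")
  if (length(empty_slices))
    warning("no body component above ", min_area, " pixels on slice(s) ",
            paste(empty_slices, collapse = ", "), "; left empty")
  body
}
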
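#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of attenuation values in Hounsfield units
#' (HU) together with the physical voxel spacing.  The canonical in-memory
#' axis order is `(slice, row, col)`; the row index increases toward the
#' patient's posterior (toward the scanner bed), matching standard axial CT
#' display.
#'
#' @param voxels numeric 3-D array of attenuation values in HU, indexed
#'   `(slice, row, col)`.
#' @param spacing numeric length-3 vector `(row_mm, col_mm, slice_mm)`:
#'   in-plane pixel sizes and slice interval in millimetres.
#' @param meta optional named list of free-form acquisition metadata.
#'
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`
#'   and `meta`.
#'
#' @details Values outside the plausible HU range \[-2048, 4096\] trigger a
#'   warning but are kept untouched: clamping, if any, happens only at
#'   reporting time, never during computation.
#'
#' @examples
#' v <- ct_volume(array(-1000, dim = c(2, 4, 4)), spacing = c(1, 1, 5))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (slice, row, col); got ",
         paste(dim(voxels), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (row_mm, col_mm, slice_mm)")
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite")
  rng <- range(voxels)
  if (rng[1] < -2048 || rng[2] > 4096)
    warning("voxel values outside plausible HU range [-2048, 4096]: ",
            rng[1], " .. ", rng[2])
  structure(
    list(voxels = voxels, spacing = spacing, meta = meta),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.3g x %.3g mm in-plane, %.3g mm slice interval\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: %.1f .. %.1f\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param spacing `(row_mm, col_mm, slice_mm)` voxel spacing.
#' @return The volume of one voxel in mL.
#' @export
voxel_volume_ml <- function(spacing) {
  prod(as.numeric(spacing)) / 1000
}

# --- binary masks -----------------------------------------------------------

#' Validate a binary mask against a reference grid
#'
#' Binary masks are plain `logical` 3-D arrays aligned to a `ct_volume` grid.
#' `as_mask()` coerces numeric 0/1 arrays and checks shape and binarity.
#'
#' @param x array to coerce (logical, or numeric containing only 0/1).
#' @param ref optional reference: a `ct_volume` or an array/mask whose
#'   dimensions `x` must match.
#' @return A logical 3-D array.
#' @export
as_mask <- function(x, ref = NULL) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("a mask must be a 3-D array; got ",
         paste(dim(x), collapse = "x"))
  if (!is.logical(x)) {
    if (!all(x %in% c(0, 1)))
      stop("mask values must be strictly binary (0/1)")
    x <- array(x != 0, dim = dim(x))
  }
  if (any(is.na(x))) stop("mask values must not be NA")
  if (!is.null(ref)) {
    rd <- if (inherits(ref, "ct_volume")) dim(ref$voxels) else dim(ref)
    if (!identical(dim(x), rd))
      stop("mask shape ", paste(dim(x), collapse = "x"),
           " does not match the reference grid ", paste(rd, collapse = "x"))
  }
  x
}

# internal: empty mask on a grid
empty_mask <- function(grid_shape) {
  array(FALSE, dim = grid_shape)
}

# internal: check two or more masks share one grid
check_same_grid <- function(...) {
  ms <- list(...)
  d0 <- dim(ms[[1]])
  for (m in ms[-1]) {
    if (!identical(dim(m), d0))
      stop("masks do not share one grid: ", paste(d0, collapse = "x"),
           " vs ", paste(dim(m), collapse = "x"))
  }
  invisible(d0)
}
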
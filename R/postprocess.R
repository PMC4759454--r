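#' Detect bones by 3-D region growing
#'
#' Seeds are all body voxels with attenuation above `bone_seed` (cortical
#' bone); growth accepts 26-connected neighbours with attenuation at or above
#' `bone_grow`, so the cortical shell and trabecular interior are captured.
#' Seeding every supra-threshold voxel keeps the pipeline fully automated
#' (no manual seed point).
#'
#' @param volume a [ct_volume].
#' @param body body mask from [detect_body_region()].
#' @param thresholds a [thresholds] object supplying `bone_seed` and
#'   `bone_grow` in HU.
#' @return Logical bone mask (empty when no voxel exceeds `bone_seed`).
#' @export
detect_bones <- function(volume, body, thresholds = ctadipose::thresholds()) {
  stopifnot(inherits(volume, "ct_volume"))
  body <- as_mask(body, volume)
  seeds <- volume$voxels > thresholds$bone_seed & body
  if (!any(seeds)) return(empty_mask(dim(volume$voxels)))
  grown <- .region_grow3d(volume$voxels, seeds, thresholds$bone_grow)
  array(grown, dim = dim(volume$voxels))
}

#' Bone correction mask
#'
#' Per slice and per 8-connected bone component, computes the component's
#' convex-hull closed path, corrects it against the component's own pixels
#' with [correct_closed_path()], and fills it.  The filled hulls cover the
#' fatty marrow enclosed by each cortical shell.  Each component is labeled
#' by its side: `POSTERIOR` when its centroid's lateral offset from the body
#' midline column is within 25% of the body half-width on that slice, else
#' `LEFT`/`RIGHT` by the sign of the offset (image left = smaller column).
#' Degenerate components (fewer than 3 pixels, or collinear) contribute
#' their raw pixels without a hull.
#'
#' @param bone bone mask from [detect_bones()].
#' @param nonfat non-fat mask from [segment_nonfat()] (kept for interface
#'   symmetry with the separation-mask construction; correction uses each
#'   component's own pixels).
#' @param body body mask, used for the midline/half-width side rule.
#' @return An object of class `bone_correction_mask` with elements `bone`,
#'   `correction` (logical mask of filled hulls) and `components` (per-slice
#'   list of records with `label`, `centroid`, `pixels`, `side`).
#' @export
build_correction_mask <- function(bone, nonfat, body) {
  bone <- as_mask(bone); nonfat <- as_mask(nonfat); body <- as_mask(body)
  d <- check_same_grid(bone, nonfat, body)
  correction <- empty_mask(d)
  components <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    bsl <- matrix(bone[s, , ], d[2], d[3])
    components[[s]] <- list()
    if (!any(bsl)) next
    body_cols <- which(apply(matrix(body[s, , ], d[2], d[3]), 2, any))
    if (length(body_cols)) {
      midline <- (min(body_cols) + max(body_cols)) / 2
      half_width <- max((max(body_cols) - min(body_cols)) / 2, 1)
    } else {
      midline <- (d[3] + 1) / 2
      half_width <- d[3] / 2
    }
    lab <- .cc_label2d8(bsl)
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      px <- which(comp, arr.ind = TRUE)
      hull <- convex_hull_path(comp, slice_index = s)
      if (is.null(hull)) {
        filled <- comp
      } else {
        corrected <- correct_closed_path(hull, comp)
        filled <- .fill_polygon_px(corrected$vertices - 1L, d[2], d[3])
      }
      filled <- filled | comp  # a component always lies inside its own record
      correction[s, , ] <- correction[s, , ] | filled
      centroid <- colMeans(px)
      offset <- centroid[2] - midline
      side <- if (abs(offset) <= 0.25 * half_width) "POSTERIOR"
              else if (offset < 0) "LEFT" else "RIGHT"
      components[[s]][[l]] <- list(label = l, centroid = unname(centroid),
                                   pixels = which(filled), side = side)
    }
  }
  structure(list(bone = bone, correction = correction, components = components),
            class = "bone_correction_mask")
}

#' Classify a slice by its bone configuration
#'
#' `AREA1` slices have lateral bone (ribs or pelvis: any `LEFT`/`RIGHT`
#' component), so the abdominal cavity is bone-bounded on the back and both
#' sides; `AREA2` slices have only posterior bone (spine); `NONE` means no
#' bone on the slice.
#'
#' @param components_for_slice one slice's component list from
#'   [build_correction_mask()].
#' @return `"AREA1"`, `"AREA2"` or `"NONE"`.
#' @export
classify_slice_area <- function(components_for_slice) {
  if (!length(components_for_slice)) return("NONE")
  sides <- vapply(components_for_slice, function(x) x$side, character(1))
  if (any(sides %in% c("LEFT", "RIGHT"))) "AREA1" else "AREA2"
}

#' Remove marrow fat falsely detected as VAT
#'
#' Fat inside bones lands in the fat attenuation band and inside the
#' separation mask, so it is wrongly counted as VAT.  On `AREA2` slices, VAT
#' voxels inside `POSTERIOR` component hulls move from `vat` to
#' `removed_bone_fat`; on `AREA1` slices, voxels inside `POSTERIOR`, `LEFT`
#' and `RIGHT` hulls move; `NONE` slices are untouched.  SAT is never
#' modified, and the corrected VAT is always a subset of the input VAT.
#'
#' @param seg a [fat_segmentation] from [split_sat_vat()].
#' @param corr a `bone_correction_mask` from [build_correction_mask()].
#' @param areas optional character vector of per-slice area classes; computed
#'   from `corr$components` with [classify_slice_area()] when missing.
#' @return The corrected [fat_segmentation].
#' @export
apply_vat_correction <- function(seg, corr, areas = NULL) {
  stopifnot(inherits(seg, "fat_segmentation"),
            inherits(corr, "bone_correction_mask"))
  d <- check_same_grid(seg$tat, corr$correction)
  if (is.null(areas))
    areas <- vapply(corr$components, classify_slice_area, character(1))
  if (length(areas) != d[1])
    stop("`areas` must hold one class per slice")
  vat <- seg$vat
  removed <- seg$removed_bone_fat
  for (s in seq_len(d[1])) {
    if (areas[s] == "NONE" || !length(corr$components[[s]])) next
    scope <- matrix(FALSE, d[2], d[3])
    for (comp in corr$components[[s]]) {
      if (areas[s] == "AREA2" && comp$side != "POSTERIOR") next
      scope[comp$pixels] <- TRUE
    }
    if (!any(scope)) next
    vsl <- matrix(vat[s, , ], d[2], d[3])
    hit <- vsl & scope
    if (!any(hit)) next
    vat[s, , ] <- vsl & !scope
    removed[s, , ] <- matrix(removed[s, , ], d[2], d[3]) | hit
  }
  fat_segmentation(tat = seg$tat, sat = seg$sat, vat = vat,
                   removed_bone_fat = removed)
}
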
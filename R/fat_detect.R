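#' Closed path on one axial slice
#'
#' An ordered polygon of integer pixel vertices `(row, col)` on one slice,
#' with an implicit closing edge from the last vertex back to the first.
#'
#' @param vertices integer matrix with columns `(row, col)`, one vertex per
#'   row, at least 3 rows.
#' @param slice_index 1-based index of the slice the path lives on.
#' @return An object of class `slice_closed_path`.
#' @export
slice_closed_path <- function(vertices, slice_index) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "integer"
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a closed path needs an n x 2 matrix of at least 3 (row, col) vertices")
  n <- nrow(vertices)
  nxt <- c(seq_len(n)[-1], 1L)
  if (any(vertices[, 1] == vertices[nxt, 1] & vertices[, 2] == vertices[nxt, 2]))
    stop("consecutive closed-path vertices must differ")
  structure(list(vertices = vertices, slice_index = as.integer(slice_index)),
            class = "slice_closed_path")
}

#' @export
print.slice_closed_path <- function(x, ...) {
  cat(sprintf("<slice_closed_path> %d vertices on slice %d\n",
              nrow(x$vertices), x$slice_index))
  invisible(x)
}

#' Detect total adipose tissue (TAT)
#'
#' TAT is every body voxel whose attenuation falls in the fat band
#' `[fat_low, fat_high]` HU, bounds inclusive.
#'
#' @param volume a [ct_volume].
#' @param body body mask from [detect_body_region()].
#' @param thresholds a [thresholds] object.
#' @return Logical TAT mask.
#' @export
detect_tat <- function(volume, body, thresholds = ctadipose::thresholds()) {
  stopifnot(inherits(volume, "ct_volume"))
  body <- as_mask(body, volume)
  hu <- volume$voxels
  band <- hu >= thresholds$fat_low & hu <= thresholds$fat_high
  array(band & body, dim = dim(hu))
}

#' Segment the non-fat region
#'
#' The non-fat region (muscle, organs, bone) anchors the separation mask.  It
#' is the body minus TAT, cleaned per slice by morphological opening with a
#' disc structuring element so the thin skin ring disappears while muscle,
#' organs and bone survive.
#'
#' @param body,tat masks on one grid.
#' @param opening_radius_mm physical radius of the opening disc in mm
#'   (default 3).  Structures thinner than about twice this radius are
#'   removed.
#' @param spacing voxel spacing `(row_mm, col_mm, slice_mm)` used to convert
#'   the radius to pixels (the mean in-plane pixel size is used).
#' @return Logical non-fat mask.
#' @export
segment_nonfat <- function(body, tat, opening_radius_mm = 3,
                           spacing = c(1, 1, 1)) {
  if (opening_radius_mm <= 0) stop("`opening_radius_mm` must be positive")
  body <- as_mask(body); tat <- as_mask(tat)
  d <- check_same_grid(body, tat)
  px <- opening_radius_mm / mean(spacing[1:2])
  size <- 2L * max(1L, as.integer(floor(px))) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  out <- empty_mask(d)
  for (s in seq_len(d[1])) {
    sl <- matrix(body[s, , ] & !tat[s, , ], d[2], d[3])
    if (!any(sl)) next
    out[s, , ] <- EBImage::opening(sl + 0, brush) > 0
  }
  out
}

# orientation of triple a, b, c given as length-2 (row, col) vectors, in the
# (x = col, y = row) frame: > 0 counter-clockwise, 0 collinear
.orient2 <- function(a, b, c) {
  (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
}

#' Convex-hull closed path of a slice's foreground
#'
#' Computes the convex hull of the foreground pixel centres of one slice and
#' returns it as a closed path.  Every foreground pixel lying exactly on the
#' hull boundary is a vertex (collinear boundary points included), ordered
#' counter-clockwise (in the `(x = col, y = row)` frame) starting from the
#' vertex with the smallest `(row, col)` in lexicographic order.
#'
#' @param nonfat_slice logical matrix (rows x cols) of foreground pixels.
#' @param slice_index slice the path belongs to (stored on the result).
#' @return A [slice_closed_path], or `NULL` when fewer than 3 non-collinear
#'   foreground pixels exist (no closed path for this slice).
#' @export
convex_hull_path <- function(nonfat_slice, slice_index = 1L) {
  pts <- which(nonfat_slice != 0, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(NULL)
  # extreme points via chull in the (x = col, y = row) frame
  idx <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(idx) < 3L) return(NULL)
  ext <- pts[idx, , drop = FALSE]
  # all collinear?
  coll <- TRUE
  for (k in seq_len(nrow(ext))[-(1:2)]) {
    if (.orient2(ext[1, ], ext[2, ], ext[k, ]) != 0) { coll <- FALSE; break }
  }
  if (coll) return(NULL)
  # orient counter-clockwise (positive shoelace area in (col, row) frame)
  n <- nrow(ext)
  area2 <- sum(ext[, 2] * ext[c(2:n, 1), 1] - ext[c(2:n, 1), 2] * ext[, 1])
  if (area2 < 0) ext <- ext[n:1, , drop = FALSE]
  # insert collinear boundary points along each edge
  verts <- NULL
  n <- nrow(ext)
  for (k in seq_len(n)) {
    a <- ext[k, ]; b <- ext[if (k == n) 1L else k + 1L, ]
    cr <- (b[2] - a[2]) * (pts[, 1] - a[1]) - (b[1] - a[1]) * (pts[, 2] - a[2])
    on <- cr == 0 &
      pts[, 1] >= pmin(a[1], b[1]) & pts[, 1] <= pmax(a[1], b[1]) &
      pts[, 2] >= pmin(a[2], b[2]) & pts[, 2] <= pmax(a[2], b[2]) &
      !(pts[, 1] == a[1] & pts[, 2] == a[2]) &
      !(pts[, 1] == b[1] & pts[, 2] == b[2])
    seg <- pts[on, , drop = FALSE]
    if (nrow(seg) > 1L) {
      d2 <- (seg[, 1] - a[1])^2 + (seg[, 2] - a[2])^2
      seg <- seg[order(d2), , drop = FALSE]
    }
    verts <- rbind(verts, matrix(a, 1), seg)
  }
  verts <- unique(verts)
  # rotate so the lexicographically smallest (row, col) vertex comes first
  start <- order(verts[, 1], verts[, 2])[1]
  if (start > 1L)
    verts <- rbind(verts[start:nrow(verts), , drop = FALSE],
                   verts[seq_len(start - 1L), , drop = FALSE])
  slice_closed_path(verts, slice_index)
}

# contact predicate helper: pixels on or 8-adjacent to foreground
.contact_mask <- function(fg) {
  EBImage::dilate(fg + 0, EBImage::makeBrush(3, shape = "box")) > 0
}

#' Correct a closed path onto the non-fat region
#'
#' The raw convex-hull path spans concavities of the muscle wall (and the
#' openings between muscle segments), so parts of it are not attached to any
#' tissue.  This correction walks every coordinate along the rasterized
#' closed path and (1) keeps coordinates that are "in contact" -- on or
#' 8-adjacent to a non-fat pixel; (2) moves a non-contact coordinate along
#' its own image column toward the centroid of the non-fat region, to the
#' first contacting position (a coordinate whose column holds no non-fat
#' pixel is deleted); (3) re-chains the corrected coordinates starting from
#' the lexicographically smallest `(row, col)`, repeatedly connecting to the
#' nearest unvisited coordinate (Euclidean distance, ties broken by smaller
#' row then smaller column).
#'
#' @param path a [slice_closed_path] from [convex_hull_path()] on the same
#'   slice.
#' @param nonfat_slice logical matrix of the non-fat region.
#' @return A corrected [slice_closed_path].  If fewer than 3 corrected
#'   coordinates remain, the uncorrected path is returned with a warning.
#' @export
correct_closed_path <- function(path, nonfat_slice) {
  stopifnot(inherits(path, "slice_closed_path"))
  fg <- nonfat_slice != 0
  pts <- .densify_path(path$vertices)
  pts <- unique(pts)
  contact <- .contact_mask(fg)
  cen_row <- mean(which(fg, arr.ind = TRUE)[, 1])
  keep <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, 1]; c <- pts[k, 2]
    if (contact[r, c]) { keep <- rbind(keep, c(r, c)); next }
    cand <- which(contact[, c])
    if (!length(cand)) next                       # column never contacts: delete
    side <- if (cen_row >= r) cand[cand >= r] else cand[cand <= r]
    newr <- if (length(side)) {
      if (cen_row >= r) min(side) else max(side)
    } else {
      cand[order(abs(cand - r), cand)][1]         # nearest overall, smaller row on tie
    }
    keep <- rbind(keep, c(newr, c))
  }
  keep <- unique(keep)
  if (nrow(keep) < 3L) {
    warning("fewer than 3 corrected coordinates remain on slice ",
            path$slice_index, "; falling back to the uncorrected path")
    return(path)
  }
  storage.mode(keep) <- "integer"
  ord <- .nn_chain(keep)
  slice_closed_path(keep[ord, , drop = FALSE], path$slice_index)
}

#' Build the separation mask from per-slice closed paths
#'
#' Rasterizes each slice's corrected closed path with a pixel-centre-in-
#' polygon rule (boundary pixels included) and stacks the filled polygons
#' into a 3-D mask.  Slices without a path stay empty.  A self-intersecting
#' chain is filled with the even-odd rule and triggers a warning.
#'
#' @param paths list of [slice_closed_path] objects (at most one per slice);
#'   `NULL` entries are ignored.
#' @param grid_shape integer `(slices, rows, cols)` of the target grid.
#' @return An object of class `separation_mask` with elements `mask`
#'   (logical 3-D array) and `paths`.
#' @export
build_separation_mask <- function(paths, grid_shape) {
  grid_shape <- as.integer(grid_shape)
  mask <- empty_mask(grid_shape)
  paths <- Filter(Negate(is.null), paths)
  seen <- integer(0)
  for (p in paths) {
    stopifnot(inherits(p, "slice_closed_path"))
    s <- p$slice_index
    if (s < 1L || s > grid_shape[1])
      stop("path slice_index ", s, " outside the grid")
    if (s %in% seen) stop("more than one closed path for slice ", s)
    seen <- c(seen, s)
    v <- p$vertices
    if (any(v[, 1] < 1L | v[, 1] > grid_shape[2] |
            v[, 2] < 1L | v[, 2] > grid_shape[3]))
      stop("closed-path vertices outside the image bounds on slice ", s)
    if (.path_self_intersects(v))
      warning("self-intersecting closed path on slice ", s,
              "; filled with the even-odd rule")
    mask[s, , ] <- .fill_polygon_px(v - 1L, grid_shape[2], grid_shape[3])
  }
  structure(list(mask = mask, paths = paths), class = "separation_mask")
}

#' Fat segmentation container
#'
#' Holds the TAT/SAT/VAT mask triple plus the marrow fat removed by the bone
#' correction, with the partition invariants `sat` disjoint from `vat` and
#' `sat | vat | removed_bone_fat == tat` enforced.
#'
#' @param tat,sat,vat,removed_bone_fat logical masks on one grid.
#' @return An object of class `fat_segmentation`.
#' @export
fat_segmentation <- function(tat, sat, vat,
                             removed_bone_fat = empty_mask(dim(tat))) {
  tat <- as_mask(tat); sat <- as_mask(sat); vat <- as_mask(vat)
  removed_bone_fat <- as_mask(removed_bone_fat)
  check_same_grid(tat, sat, vat, removed_bone_fat)
  if (any(sat & vat)) stop("sat and vat overlap")
  if (!identical(sat | vat | removed_bone_fat, tat))
    stop("sat, vat and removed_bone_fat must partition tat")
  structure(list(tat = tat, sat = sat, vat = vat,
                 removed_bone_fat = removed_bone_fat),
            class = "fat_segmentation")
}

#' @export
print.fat_segmentation <- function(x, ...) {
  cat(sprintf("<fat_segmentation> |TAT| = %d, |SAT| = %d, |VAT| = %d, removed bone fat = %d voxels\n",
              sum(x$tat), sum(x$sat), sum(x$vat), sum(x$removed_bone_fat)))
  invisible(x)
}

#' Split TAT into SAT and VAT with the separation mask
#'
#' SAT is TAT outside the separation mask; VAT is TAT inside it (logical AND).
#'
#' @param tat TAT mask from [detect_tat()].
#' @param sep a `separation_mask` from [build_separation_mask()] (or a bare
#'   logical mask).
#' @return A [fat_segmentation] with `removed_bone_fat` empty.
#' @export
split_sat_vat <- function(tat, sep) {
  m <- if (inherits(sep, "separation_mask")) sep$mask else as_mask(sep)
  tat <- as_mask(tat)
  check_same_grid(tat, m)
  fat_segmentation(tat = tat, sat = tat & !m, vat = tat & m)
}
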
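# run code under a temporary RNG state, restoring the caller's seed
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic abdominal CT phantom
#'
#' Describes an axial abdominal CT phantom as nested elliptical compartments:
#' skin ring, subcutaneous fat ring, abdominal-wall muscle ring (optionally
#' interrupted by angular gaps that connect SAT and VAT, as the linea alba
#' and wall openings do), and a visceral region holding organ tissue,
#' visceral fat blobs, a vertebra (cortical shell with fatty marrow) and
#' optional rib arcs, over an air background with a scanner-bed slab.
#'
#' Angles are measured in degrees in the axial plane with 90 deg at the
#' anterior midline (top of the image) and 270 deg posterior.
#'
#' @param grid_shape integer `(slices, rows, cols)` (default `c(24, 256, 256)`).
#' @param spacing voxel spacing `(row_mm, col_mm, slice_mm)` in mm
#'   (default `c(1.5, 1.5, 5)`).
#' @param body_semiaxes_mm body ellipse semi-axes `(row, col)` in mm.
#' @param center_row_px,center_col_px body centre in pixels (defaults leave
#'   room for the bed below the body).
#' @param skin_mm,sat_mm,muscle_mm ring thicknesses in mm.
#' @param gap_deg list of `c(start, end)` angular intervals (degrees) where
#'   the muscle ring is absent and filled with fat.
#' @param n_blobs number of visceral fat blobs.
#' @param blob_r_mm range `c(min, max)` of blob semi-axis lengths in mm.
#' @param spine_offset_frac spine centre offset toward posterior, as a
#'   fraction of the inner-region row semi-axis.
#' @param spine_r_mm outer radius of the vertebra in mm.
#' @param spine_shell_mm cortical shell thickness in mm.
#' @param ribs logical, recycled per slice: paint lateral rib arcs.
#' @param bed logical: paint the scanner-bed slab.
#' @param gas logical: carve a bowel-gas pocket (air attenuation) inside the
#'   visceral region.
#' @param hu named numeric vector of nominal attenuations per compartment
#'   (`air`, `bed`, `skin`, `sat`, `muscle`, `organ`, `vat`, `bone`,
#'   `marrow`), chosen to sit comfortably inside the standard threshold
#'   bands.
#' @param noise_sd additive Gaussian noise standard deviation in HU.
#' @param seed RNG seed; the phantom is a deterministic function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 256, 256),
                         spacing = c(1.5, 1.5, 5),
                         body_semiaxes_mm = c(95, 140),
                         center_row_px = NULL, center_col_px = NULL,
                         skin_mm = 2, sat_mm = 15, muscle_mm = 8,
                         gap_deg = list(),
                         n_blobs = 36, blob_r_mm = c(10, 24),
                         spine_offset_frac = 0.55, spine_r_mm = 16,
                         spine_shell_mm = 4,
                         ribs = FALSE, bed = TRUE, gas = FALSE,
                         hu = c(air = -1000, bed = -600, skin = 20,
                                sat = -100, muscle = 45, organ = 40,
                                vat = -100, bone = 1200, marrow = -80),
                         noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be positive (slices, rows, cols)")
  inner <- body_semiaxes_mm - (skin_mm + sat_mm + muscle_mm)
  if (any(inner <= spine_r_mm))
    stop("rings do not nest: skin + SAT + muscle thickness leaves no visceral region")
  th <- thresholds()
  fat_hus <- hu[c("sat", "vat", "marrow")]
  if (any(fat_hus < th$fat_low | fat_hus > th$fat_high))
    stop("fat compartment attenuations must lie inside the fat band")
  if (hu[["bone"]] <= th$bone_seed)
    stop("bone shell attenuation must exceed the bone seed threshold")
  spec <- list(grid_shape = grid_shape, spacing = as.numeric(spacing),
               body_semiaxes_mm = as.numeric(body_semiaxes_mm),
               center_row_px = center_row_px, center_col_px = center_col_px,
               skin_mm = skin_mm, sat_mm = sat_mm, muscle_mm = muscle_mm,
               gap_deg = gap_deg, n_blobs = as.integer(n_blobs),
               blob_r_mm = as.numeric(blob_r_mm),
               spine_offset_frac = spine_offset_frac,
               spine_r_mm = spine_r_mm, spine_shell_mm = spine_shell_mm,
               ribs = ribs, bed = bed, gas = gas, hu = hu,
               noise_sd = noise_sd, seed = as.integer(seed))
  structure(spec, class = "phantom_spec")
}

# angle in degrees in [0, 360): 90 = anterior (small rows), 270 = posterior
.axial_angle <- function(X, Y) {
  a <- atan2(-Y, X) * 180 / pi
  (a + 360) %% 360
}

.in_sector <- function(theta, lo, hi) {
  lo <- lo %% 360; hi <- hi %% 360
  if (lo <= hi) theta >= lo & theta <= hi else theta >= lo | theta <= hi
}

#' Generate a synthetic abdominal CT phantom with ground truth
#'
#' Paints the compartments of a [phantom_spec] in nesting order and returns
#' the HU volume together with exact voxel-level ground truth for every
#' compartment.  Marrow fat is part of the TAT truth but of neither SAT nor
#' VAT truth -- it is exactly the error the bone correction mask must remove,
#' so it is stored in the `removed_bone_fat` slot of the truth segmentation.
#' Ground truth is defined pre-noise; generation is deterministic given the
#' spec's seed and never calls any segmentation code.
#'
#' @param spec a [phantom_spec].
#' @return A list with `volume` (a [ct_volume]), `truth` (a
#'   [fat_segmentation]: `sat`/`vat` truth with marrow fat in
#'   `removed_bone_fat`), `body_truth`, `skin_truth`, `bone_truth`,
#'   `marrow_fat_truth`, and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(2, 96, 96),
#'                                     spacing = c(3, 3, 5)))
#' ph$volume
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  nr <- d[2]; nc <- d[3]
  cr <- if (is.null(spec$center_row_px)) 0.46 * (nr + 1) else spec$center_row_px
  cc <- if (is.null(spec$center_col_px)) (nc + 1) / 2 else spec$center_col_px
  row_mm <- spec$spacing[1]; col_mm <- spec$spacing[2]
  Y <- matrix((seq_len(nr) - cr) * row_mm, nr, nc)        # +Y toward posterior
  X <- matrix((seq_len(nc) - cc) * col_mm, nr, nc, byrow = TRUE)
  theta <- .axial_angle(X, Y)
  ell <- function(ar, ac) (Y / ar)^2 + (X / ac)^2 <= 1
  a <- spec$body_semiaxes_mm  # (row, col)
  body <- ell(a[1], a[2])
  skin_in <- ell(a[1] - spec$skin_mm, a[2] - spec$skin_mm)
  sat_in <- ell(a[1] - spec$skin_mm - spec$sat_mm,
                a[2] - spec$skin_mm - spec$sat_mm)
  inner_a <- a - (spec$skin_mm + spec$sat_mm + spec$muscle_mm)
  musc_in <- ell(inner_a[1], inner_a[2])

  # base 2-D compartment labels, identical on every slice
  # 1 air, 2 bed, 3 skin, 4 sat, 5 muscle, 6 organ, 7 vat, 8 bone, 9 marrow, 10 gas
  base <- matrix(1L, nr, nc)
  base[body & !skin_in] <- 3L
  base[skin_in & !sat_in] <- 4L
  band <- sat_in & !musc_in
  base[band] <- 5L
  for (g in spec$gap_deg)
    base[band & .in_sector(theta, g[1], g[2])] <- 4L   # gap fat joins SAT
  base[musc_in] <- 6L

  # spine: circular vertebra toward the posterior of the visceral region
  sp_y <- spec$spine_offset_frac * inner_a[1]
  spine_out <- ((Y - sp_y)^2 + X^2) <= spec$spine_r_mm^2
  spine_mar <- ((Y - sp_y)^2 + X^2) <= (spec$spine_r_mm - spec$spine_shell_mm)^2
  base[spine_out] <- 8L
  base[spine_mar] <- 9L

  # ribs intersect an axial slice as short arc segments, two per side
  rib_band <- band & (.in_sector(theta, 345, 357) | .in_sector(theta, 3, 15) |
                      .in_sector(theta, 165, 177) | .in_sector(theta, 183, 195))

  # bed slab below the body
  if (isTRUE(spec$bed)) {
    r0 <- min(nr, floor(cr + (a[1] / row_mm)) + 12L)
    bed_rows <- r0:min(nr, r0 + 5L)
    bed_cols <- floor(nc * 0.15):ceiling(nc * 0.85)
    base[bed_rows, bed_cols] <- 2L
  }

  # gas pocket in the anterior-left visceral region
  if (isTRUE(spec$gas)) {
    gx <- -0.45 * inner_a[2]; gy <- -0.45 * inner_a[1]
    gasm <- (((Y - gy) / 12)^2 + ((X - gx) / 16)^2) <= 1 & base == 6L
    base[gasm] <- 10L
  }

  ribs_on <- rep_len(as.logical(spec$ribs), d[1])
  labels <- array(0L, dim = d)

  blobs <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_blobs), function(i) {
      u <- runif(1, 0.1, 0.7); phi <- runif(1, 0, 2 * pi)
      br <- runif(2, spec$blob_r_mm[1], spec$blob_r_mm[2])
      s0 <- sample.int(d[1], 1)
      s1 <- min(d[1], s0 + sample.int(d[1], 1) - 1L)
      list(x = u * inner_a[2] * cos(phi), y = u * inner_a[1] * sin(phi),
           r = br, s = c(s0, s1))
    })
  })
  # visceral fat never encroaches on the vertebra: keep a safety margin so the
  # bone correction hull cannot cover true VAT
  spine_margin <- ((Y - sp_y)^2 + X^2) <= (spec$spine_r_mm + 3)^2

  for (s in seq_len(d[1])) {
    sl <- base
    if (ribs_on[s]) sl[rib_band] <- 8L
    for (b in blobs) {
      if (s < b$s[1] || s > b$s[2]) next
      bm <- (((Y - b$y) / b$r[1])^2 + ((X - b$x) / b$r[2])^2) <= 1 &
        sl == 6L & !spine_margin
      sl[bm] <- 7L
    }
    labels[s, , ] <- sl
  }

  hu_of <- c(spec$hu[["air"]], spec$hu[["bed"]], spec$hu[["skin"]],
             spec$hu[["sat"]], spec$hu[["muscle"]], spec$hu[["organ"]],
             spec$hu[["vat"]], spec$hu[["bone"]], spec$hu[["marrow"]],
             spec$hu[["air"]])
  vox <- array(hu_of[labels], dim = d)
  if (spec$noise_sd > 0)
    vox <- vox + with_seed(spec$seed + 1L,
                           array(rnorm(length(vox), 0, spec$noise_sd), dim = d))

  sat_t <- labels == 4L
  vat_t <- labels == 7L
  mar_t <- labels == 9L
  truth <- fat_segmentation(tat = sat_t | vat_t | mar_t, sat = sat_t,
                            vat = vat_t, removed_bone_fat = mar_t)
  list(volume = ct_volume(vox, spec$spacing,
                          meta = list(phantom_seed = spec$seed)),
       truth = truth,
       body_truth = labels >= 3L,
       skin_truth = labels == 3L,
       bone_truth = labels == 8L,
       marrow_fat_truth = mar_t,
       spec = spec)
}

#' Standard phantom battery
#'
#' A fixed, seeded suite covering the geometries the pipeline must handle:
#' (a) clean convex body without muscle gaps; (b) muscle ring interrupted by
#' two anterior gaps; (c) spine-only slices (posterior bone only); (d)
#' spine-plus-ribs slices (lateral bone); (e) a noisy variant of (b) with
#' 10 HU Gaussian noise.  All specs use the default 24 x 256 x 256 grid.
#'
#' @return Named list of [phantom_spec] objects (`a` .. `e`).
#' @export
default_suite <- function() {
  gaps <- list(c(75, 88), c(92, 105))
  list(
    a = phantom_spec(seed = 11L),
    b = phantom_spec(gap_deg = gaps, seed = 22L),
    c = phantom_spec(gap_deg = gaps, ribs = FALSE, seed = 33L),
    d = phantom_spec(gap_deg = gaps, ribs = TRUE, seed = 44L),
    e = phantom_spec(gap_deg = gaps, noise_sd = 10, seed = 55L)
  )
}
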
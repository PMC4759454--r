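ph <- generate_phantom(small_spec(ribs = TRUE, seed = 13L))
th <- thresholds()
body <- detect_body_region(ph$volume, th)
tat <- detect_tat(ph$volume, body, th)
nonfat <- segment_nonfat(body, tat, 3, ph$volume$spacing)

test_that("no voxel above the seed threshold means no bone", {
  v <- ct_volume(array(40, dim = c(2, 10, 10)), c(1, 1, 5))
  b <- array(TRUE, dim = c(2, 10, 10))
  expect_identical(sum(detect_bones(v, b, th)), 0L)
})

test_that("region growing captures the cortical shell exactly on the phantom", {
  bones <- detect_bones(ph$volume, body, th)
  expect_identical(bones, ph$bone_truth)
  # marrow sits below the growth threshold and is excluded from bone
  expect_identical(sum(bones & ph$marrow_fat_truth), 0L)
})

test_that("with equal grow and seed thresholds, growth equals seeded 26-connected components", {
  set.seed(202)
  for (k in 1:5) {
    hu <- array(runif(32^3, 0, 1250), dim = c(32, 32, 32))
    v <- ct_volume(hu, c(1, 1, 1))
    b <- array(TRUE, dim = dim(hu))
    teq <- thresholds(bone_seed = 1000, bone_grow = 1000)
    got <- detect_bones(v, b, teq)
    ora <- oracle_seeded_components(hu >= 1000, hu > 1000)
    expect_identical(got, ora)
  }
})

test_that("growth from sparse seeds matches the component oracle with a lower grow threshold", {
  set.seed(303)
  hu <- array(runif(32^3, 0, 1600), dim = c(32, 32, 32))
  v <- ct_volume(hu, c(1, 1, 1))
  b <- array(TRUE, dim = dim(hu))
  tsp <- thresholds(bone_seed = 1500, bone_grow = 1200)
  got <- detect_bones(v, b, tsp)
  ora <- oracle_seeded_components(hu >= 1200, hu > 1500)
  expect_identical(got, ora)
})

test_that("bone correction hulls cover shell plus marrow and sides are labeled", {
  bones <- detect_bones(ph$volume, body, th)
  corr <- build_correction_mask(bones, nonfat, body)
  expect_identical(sum(bones & !corr$correction), 0L)       # bone inside correction
  expect_identical(sum(ph$marrow_fat_truth & !corr$correction), 0L)  # marrow covered
  d <- dim(bones)
  for (s in seq_len(d[1])) {
    comps <- corr$components[[s]]
    sides <- vapply(comps, function(x) x$side, character(1))
    expect_setequal(unique(sides), c("POSTERIOR", "LEFT", "RIGHT"))
    # each component's filled hull contains its bone pixels by construction
    for (cp in comps) expect_true(length(cp$pixels) > 0)
  }
})

test_that("side labels follow the 25% half-width midline rule", {
  d <- c(1, 40, 80)
  bone <- array(FALSE, d)
  bone[1, 30:32, 38:42] <- TRUE   # centred: posterior
  bone[1, 18:20, 6:9] <- TRUE     # far left
  bone[1, 18:20, 72:75] <- TRUE   # far right
  bodym <- array(FALSE, d); bodym[1, 5:38, 3:78] <- TRUE
  corr <- build_correction_mask(bone, bone, bodym)
  sides <- sort(vapply(corr$components[[1]], function(x) x$side, character(1)))
  expect_identical(sides, c("LEFT", "POSTERIOR", "RIGHT"))
})

test_that("slice area classification follows the component sides", {
  mk <- function(sides) lapply(sides, function(s) list(side = s))
  expect_identical(classify_slice_area(mk(c("POSTERIOR"))), "AREA2")
  expect_identical(classify_slice_area(mk(c("POSTERIOR", "LEFT", "RIGHT"))), "AREA1")
  expect_identical(classify_slice_area(mk(c("RIGHT"))), "AREA1")
  expect_identical(classify_slice_area(list()), "NONE")
})

test_that("VAT correction removes marrow fat, conserves counts, and is idempotent", {
  res <- segment_fat(ph$volume)
  seg0 <- res$seg_uncorrected
  seg <- res$seg
  # marrow fat was inside the uncorrected VAT and is gone afterwards
  expect_gt(sum(seg0$vat & ph$marrow_fat_truth), 0L)
  expect_identical(sum(seg$vat & ph$marrow_fat_truth), 0L)
  # conservation and monotonicity
  expect_identical(seg$sat, seg0$sat)
  expect_identical(sum(seg$vat) + sum(seg$removed_bone_fat), sum(seg0$vat))
  expect_identical(sum(seg$vat & !seg0$vat), 0L)
  # idempotence
  again <- apply_vat_correction(seg, res$correction, res$areas)
  expect_identical(again$vat, seg$vat)
  expect_identical(again$removed_bone_fat, seg$removed_bone_fat)
})

test_that("an empty correction mask leaves the segmentation unchanged", {
  res <- segment_fat(ph$volume)
  seg0 <- res$seg_uncorrected
  d <- dim(seg0$tat)
  empty_corr <- build_correction_mask(array(FALSE, d), nonfat, body)
  out <- apply_vat_correction(seg0, empty_corr)
  expect_identical(out$vat, seg0$vat)
  expect_identical(out$sat, seg0$sat)
})

test_that("AREA2 slices only strip fat inside posterior hulls", {
  d <- c(1, 40, 80)
  vox <- array(-1000, dim = d)
  bodym <- array(FALSE, d); bodym[1, 3:38, 3:78] <- TRUE
  vox[bodym] <- -100                                   # fat everywhere in body
  tatm <- array(vox == -100, dim = d)
  seg0 <- split_sat_vat(tatm, array(TRUE, dim = d))    # all fat as VAT
  bone <- array(FALSE, d)
  bone[1, 28:34, 36:44] <- TRUE; bone[1, 30:32, 38:42] <- FALSE  # posterior ring
  bone[1, 10:12, 70:74] <- TRUE                        # lateral component
  vox[bone] <- 1200
  corr <- build_correction_mask(bone, bone, bodym)
  # force AREA2: only posterior hulls act, the lateral hull is ignored
  out <- apply_vat_correction(seg0, corr, areas = "AREA2")
  expect_identical(sum(out$removed_bone_fat[1, 30:32, 38:42]), 15L)
  expect_identical(sum(out$removed_bone_fat[1, 10:12, 70:74]), 0L)
  # under AREA1 both act
  out1 <- apply_vat_correction(seg0, corr, areas = "AREA1")
  expect_gt(sum(out1$removed_bone_fat), sum(out$removed_bone_fat))
})
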
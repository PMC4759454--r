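test_that("noise-free phantoms take exactly the nominal compartment attenuations", {
  ph <- generate_phantom(small_spec(seed = 1L))
  expect_identical(sort(unique(as.vector(ph$volume$voxels))),
                   sort(unique(unname(ph$spec$hu))))
  # each truth compartment is painted with its own nominal HU
  expect_true(all(ph$volume$voxels[ph$truth$sat] == ph$spec$hu[["sat"]]))
  expect_true(all(ph$volume$voxels[ph$truth$vat] == ph$spec$hu[["vat"]]))
  expect_true(all(ph$volume$voxels[ph$marrow_fat_truth] == ph$spec$hu[["marrow"]]))
  expect_true(all(ph$volume$voxels[ph$bone_truth] == ph$spec$hu[["bone"]]))
})

test_that("the same seed reproduces the phantom bit for bit", {
  a <- generate_phantom(small_spec(noise_sd = 5, seed = 42L))
  b <- generate_phantom(small_spec(noise_sd = 5, seed = 42L))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$vat, b$truth$vat)
  c <- generate_phantom(small_spec(noise_sd = 5, seed = 43L))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("phantom generation leaves the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(generate_phantom(small_spec(seed = 9L)))
  expect_identical(.Random.seed, before)
})

test_that("truth masks partition TAT with marrow fat outside SAT and VAT", {
  ph <- generate_phantom(small_spec(ribs = TRUE, gas = TRUE, seed = 5L))
  t <- ph$truth
  expect_identical(sum(t$sat & t$vat), 0L)
  expect_identical(t$sat | t$vat | t$removed_bone_fat, t$tat)
  expect_identical(t$removed_bone_fat, ph$marrow_fat_truth)
  expect_identical(sum(t$sat & ph$marrow_fat_truth), 0L)
  expect_identical(sum(t$vat & ph$marrow_fat_truth), 0L)
  # nesting: every painted compartment lies inside the body
  expect_identical(sum(t$tat & !ph$body_truth), 0L)
  expect_identical(sum(ph$bone_truth & !ph$body_truth), 0L)
  expect_identical(sum(ph$skin_truth & t$tat), 0L)
})

test_that("the visceral fat load resembles an abdominal cohort", {
  ph <- generate_phantom(phantom_spec(seed = 77L))
  ratio <- sum(ph$truth$vat) / sum(ph$truth$sat)
  expect_gt(ratio, 0.4)   # visceral fat is a substantial fraction of SAT
  expect_lt(ratio, 1.2)
})

test_that("non-nesting specs are rejected", {
  expect_error(phantom_spec(body_semiaxes_mm = c(30, 40), sat_mm = 25,
                            muscle_mm = 10), "nest")
  expect_error(phantom_spec(hu = c(air = -1000, bed = -600, skin = 20,
                                   sat = -300, muscle = 45, organ = 40,
                                   vat = -100, bone = 1200, marrow = -80)),
               "fat band")
  expect_error(phantom_spec(hu = c(air = -1000, bed = -600, skin = 20,
                                   sat = -100, muscle = 45, organ = 40,
                                   vat = -100, bone = 800, marrow = -80)),
               "bone")
})

test_that("the default suite covers the study geometries", {
  suite <- default_suite()
  expect_gte(length(suite), 5L)
  expect_identical(names(suite), c("a", "b", "c", "d", "e"))
  expect_true(all(vapply(suite[c("a", "b", "c", "d")],
                         function(s) s$noise_sd == 0, logical(1))))
  expect_gt(suite$e$noise_sd, 0)
  expect_identical(length(suite$a$gap_deg), 0L)
  expect_gte(length(suite$b$gap_deg), 2L)
  expect_false(isTRUE(suite$c$ribs))
  expect_true(isTRUE(suite$d$ribs))
  # spec (d) has lateral rib components on at least one slice
  ph <- generate_phantom(suite$d)
  lat <- FALSE
  d <- dim(ph$bone_truth)
  mid_col <- (d[3] + 1) / 2
  for (s in seq_len(d[1])) {
    px <- which(matrix(ph$bone_truth[s, , ], d[2], d[3]), arr.ind = TRUE)
    if (nrow(px) && (min(px[, 2]) < mid_col - 50 || max(px[, 2]) > mid_col + 50))
      lat <- TRUE
  }
  expect_true(lat)
})
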
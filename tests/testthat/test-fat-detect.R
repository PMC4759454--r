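ph <- generate_phantom(small_spec(seed = 7L))
th <- thresholds()
body <- detect_body_region(ph$volume, th)
tat <- detect_tat(ph$volume, body, th)

test_that("TAT is the inclusive fat band gated by the body mask", {
  v <- array(0, dim = c(1, 2, 3))
  v[1, 1, ] <- c(-100, -29, -190)   # in, out (above), in (lower bound)
  v[1, 2, ] <- c(-191, -30, -100)   # out (below), in (upper bound), in
  b <- array(TRUE, dim = dim(v)); b[1, 2, 3] <- FALSE  # body gate
  got <- detect_tat(ct_volume(v, c(1, 1, 1)), b, th)
  expect_identical(got[1, 1, ], c(TRUE, FALSE, TRUE))
  expect_identical(got[1, 2, ], c(FALSE, TRUE, FALSE))  # -100 outside body
})

test_that("phantom TAT count equals the constructed fat voxel count", {
  expect_identical(sum(tat), sum(ph$truth$tat))
  expect_identical(tat & ph$body_truth, tat)  # never outside the body
})

test_that("non-fat segmentation removes the skin ring but keeps the wall", {
  nonfat <- segment_nonfat(body, tat, 3, ph$volume$spacing)
  expect_identical(sum(nonfat & ph$skin_truth), 0L)
  # the muscle wall must survive the opening on every slice
  muscle <- ph$body_truth & !ph$truth$tat & !ph$skin_truth & !ph$bone_truth &
    !ph$marrow_fat_truth
  expect_gt(sum(nonfat & muscle) / sum(muscle), 0.7)
  expect_error(segment_nonfat(body, tat, 0, ph$volume$spacing), "positive")
  expect_error(segment_nonfat(body, tat, -2, ph$volume$spacing), "positive")
})

test_that("non-fat of an empty TAT is the opened body; empty body gives nothing", {
  d <- dim(body)
  none <- array(FALSE, dim = d)
  expect_identical(segment_nonfat(body, none, 3, ph$volume$spacing) |> sum() > 0, TRUE)
  op_body <- segment_nonfat(body, none, 3, ph$volume$spacing)
  # opening of (body \ empty) = opening of body: recompute via EBImage directly
  brush <- EBImage::makeBrush(5, "disc")
  ref <- array(FALSE, dim = d)
  for (s in seq_len(d[1]))
    ref[s, , ] <- EBImage::opening(matrix(body[s, , ], d[2], d[3]) + 0, brush) > 0
  expect_identical(op_body, ref)
  expect_identical(segment_nonfat(none, none, 3, ph$volume$spacing), none)
})

test_that("contact correction is the identity movement on a convex region", {
  # solid digital ellipse: every path coordinate is in contact already
  m <- matrix(FALSE, 41, 41)
  for (r in 1:41) for (c in 1:41)
    m[r, c] <- ((r - 21) / 14)^2 + ((c - 21) / 18)^2 <= 1
  h <- convex_hull_path(m, 1L)
  corr <- correct_closed_path(h, m)
  # all hull vertices are retained and nothing moved off the densified path
  dens <- canon_pts(unique(ctadipose:::.densify_path(h$vertices)))
  expect_identical(canon_pts(corr$vertices), dens)
  expect_true(all(canon_pts(h$vertices) %in% dens))
})

test_that("the C-shaped fixture corrects exactly as hand-traced", {
  m <- matrix(FALSE, 9, 9)
  m[3:7, 3] <- TRUE; m[3:7, 7] <- TRUE; m[7, 3:7] <- TRUE
  h <- convex_hull_path(m, 1L)
  # the only path coordinate not in contact spans the opening at (3, 5);
  # it moves down its column to the first contacting position (6, 5)
  corr <- correct_closed_path(h, m)
  expected <- rbind(
    c(3, 3), c(3, 4), c(4, 3), c(5, 3), c(6, 3), c(7, 3), c(7, 4), c(7, 5),
    c(6, 5), c(7, 6), c(7, 7), c(6, 7), c(5, 7), c(4, 7), c(3, 7), c(3, 6))
  storage.mode(expected) <- "integer"
  expect_identical(unname(corr$vertices), expected)
})

test_that("corrected coordinates satisfy the contact predicate and keep their column", {
  set.seed(11)
  for (k in 1:5) {
    m <- matrix(FALSE, 40, 40)
    # blobby region with a concavity
    for (r in 1:40) for (c in 1:40) {
      m[r, c] <- ((r - 22) / 12)^2 + ((c - 20) / 15)^2 <= 1
    }
    gap_cols <- sample(10:30, 8)
    m[1:14, gap_cols] <- FALSE   # carve notches from the top
    h <- convex_hull_path(m, 1L)
    corr <- correct_closed_path(h, m)
    contact <- ctadipose:::.contact_mask(m)
    expect_true(all(contact[corr$vertices]))
    # every corrected coordinate shares a column with some original path coordinate
    dens <- ctadipose:::.densify_path(h$vertices)
    expect_true(all(corr$vertices[, 2] %in% dens[, 2]))
  }
})

test_that("correction falls back to the raw hull when too little contact remains", {
  m <- matrix(FALSE, 9, 9)
  m[2, 2] <- m[2, 8] <- m[8, 5] <- TRUE
  h <- convex_hull_path(m, 1L)
  # shrink the region after the fact so (almost) nothing contacts
  m2 <- matrix(FALSE, 9, 9)
  expect_warning(corr <- correct_closed_path(h, m2), "falling back")
  expect_identical(corr$vertices, h$vertices)
})

test_that("separation-mask rasterization matches inclusive pixel-centre filling", {
  sq <- slice_closed_path(rbind(c(3, 3), c(3, 7), c(7, 7), c(7, 3)), 1L)
  m <- build_separation_mask(list(sq), c(1, 9, 9))$mask
  expect_identical(sum(m), 25L)
  expect_identical(which(m[1, , ], arr.ind = TRUE) |> canon_pts(),
                   canon_pts(as.matrix(expand.grid(3:7, 3:7))))

  tri <- slice_closed_path(rbind(c(1, 1), c(1, 3), c(3, 1)), 2L)
  m2 <- build_separation_mask(list(tri), c(2, 3, 3))$mask
  expect_identical(canon_pts(which(m2[2, , ], arr.ind = TRUE)),
                   canon_pts(rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1),
                                   c(2, 2), c(3, 1))))
  # and agrees with the brute-force point-in-polygon oracle
  expect_identical(m2[2, , ], oracle_fill(rbind(c(1, 1), c(1, 3), c(3, 1)), 3, 3))
  expect_identical(m2[1, , ], matrix(FALSE, 3, 3))  # slice without a path

  empty <- build_separation_mask(list(), c(3, 5, 5))$mask
  expect_identical(sum(empty), 0L)
})

test_that("random polygons rasterize identically to the point-in-polygon oracle", {
  set.seed(23)
  for (k in 1:8) {
    mask <- matrix(FALSE, 12, 12)
    mask[sample(144, 15)] <- TRUE
    h <- convex_hull_path(mask, 1L)
    if (is.null(h)) next
    got <- build_separation_mask(list(h), c(1, 12, 12))$mask[1, , ]
    expect_identical(got, oracle_fill(h$vertices, 12, 12))
  }
})

test_that("a self-intersecting chain fills with the even-odd rule and warns", {
  bow <- slice_closed_path(rbind(c(1, 1), c(5, 5), c(1, 5), c(5, 1)), 1L)
  expect_warning(m <- build_separation_mask(list(bow), c(1, 6, 6)),
                 "self-intersecting")
  expect_identical(m$mask[1, , ], oracle_fill(rbind(c(1, 1), c(5, 5), c(1, 5), c(5, 1)), 6, 6))
})

test_that("split_sat_vat conserves TAT and honours degenerate masks", {
  d <- dim(tat)
  full <- array(TRUE, dim = d)
  seg_full <- split_sat_vat(tat, full)
  expect_identical(sum(seg_full$sat), 0L)
  expect_identical(seg_full$vat, tat)
  seg_none <- split_sat_vat(tat, array(FALSE, dim = d))
  expect_identical(seg_none$sat, tat)
  expect_identical(sum(seg_none$vat), 0L)
  # conservation on a real separation mask
  nonfat <- segment_nonfat(body, tat, 3, ph$volume$spacing)
  paths <- lapply(seq_len(d[1]), function(s) {
    h <- convex_hull_path(matrix(nonfat[s, , ], d[2], d[3]), s)
    if (is.null(h)) NULL else correct_closed_path(h, matrix(nonfat[s, , ], d[2], d[3]))
  })
  sep <- build_separation_mask(paths, d)
  seg <- split_sat_vat(tat, sep)
  expect_identical(sum(seg$sat) + sum(seg$vat), sum(tat))
  expect_identical(sum(seg$sat & seg$vat), 0L)
})

test_that("fat segmentation invariants are enforced", {
  d <- c(2, 3, 3)
  tat1 <- array(TRUE, d); sat1 <- array(FALSE, d); sat1[1, , ] <- TRUE
  vat1 <- !sat1
  expect_s3_class(fat_segmentation(tat1, sat1, vat1), "fat_segmentation")
  expect_error(fat_segmentation(tat1, sat1, tat1), "overlap")
  expect_error(fat_segmentation(tat1, sat1, array(FALSE, d)), "partition")
})
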
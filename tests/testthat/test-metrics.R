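test_that("volume arithmetic is exact voxel-count times voxel-volume", {
  mk <- function(n, d = c(10, 10, 10)) {
    m <- array(FALSE, dim = d)
    if (n > 0) m[seq_len(n)] <- TRUE
    m
  }
  seg <- fat_segmentation(tat = mk(1000), sat = mk(1000),
                          vat = mk(0))
  expect_identical(compute_volumes(seg, c(1, 1, 1))$sat_ml, 1.0)
  expect_identical(compute_volumes(seg, c(0.5, 0.5, 5))$sat_ml, 1.25)
  expect_identical(compute_volumes(seg, c(0.5, 0.5, 5))$tat_ml, 1.25)
  empty <- fat_segmentation(mk(0), mk(0), mk(0))
  v0 <- compute_volumes(empty, c(0.7, 0.7, 2.5))
  expect_identical(c(v0$tat_ml, v0$sat_ml, v0$vat_ml), c(0, 0, 0))
})

test_that("marrow fat is excluded from all volume totals", {
  d <- c(4, 6, 6)
  tat <- array(FALSE, d); tat[1:40] <- TRUE
  sat <- array(FALSE, d); sat[1:20] <- TRUE
  vat <- array(FALSE, d); vat[21:30] <- TRUE
  rem <- array(FALSE, d); rem[31:40] <- TRUE
  v <- compute_volumes(fat_segmentation(tat, sat, vat, rem), c(1, 1, 1))
  expect_equal(v$tat_ml, 30 / 1000)
  expect_equal(v$sat_ml + v$vat_ml, v$tat_ml)
})

test_that("confusion counts match an exhaustive voxel loop and respect the domain", {
  set.seed(42)
  d <- c(20, 20, 20)
  pred <- array(runif(prod(d)) < 0.3, dim = d)
  truth <- array(runif(prod(d)) < 0.25, dim = d)
  domain <- array(runif(prod(d)) < 0.8, dim = d)
  got <- confusion(pred, truth, domain)
  ora <- oracle_confusion(pred, truth, domain)
  expect_identical(got$tp, ora$tp)
  expect_identical(got$fp, ora$fp)
  expect_identical(got$tn, ora$tn)
  expect_identical(got$fn, ora$fn)
  expect_identical(got$tp + got$fp + got$tn + got$fn, sum(domain))

  # degenerate cases
  all1 <- array(TRUE, dim = d)
  c1 <- confusion(all1, all1, all1)
  expect_identical(c(c1$fp, c1$fn, c1$tn), c(0L, 0L, 0L))
  c2 <- confusion(array(FALSE, d), truth, all1)
  expect_identical(c2$fn, sum(truth))
  expect_identical(c2$tp, 0L)
  expect_error(confusion(pred, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("evaluate_counts reproduces the closed-form metric values", {
  m <- evaluate_counts(confusion_counts(tp = 90, fp = 10, tn = 890, fn = 10))
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 100 * 890 / 900)
  expect_equal(m$accuracy, 98)
  expect_equal(m$dsc, 0.9)

  perfect <- evaluate_counts(confusion_counts(50, 0, 50, 0))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))
  expect_equal(perfect$dsc, 1.0)

  worst <- evaluate_counts(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$dsc, 0)
})

test_that("0/0 metric ratios are undefined, not zero, and all-zero counts error", {
  m <- evaluate_counts(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m$sensitivity))   # no positives anywhere
  expect_true(is.na(m$dsc))
  expect_equal(m$specificity, 100)
  m2 <- evaluate_counts(confusion_counts(tp = 5, fp = 0, tn = 0, fn = 0))
  expect_true(is.na(m2$specificity))
  expect_error(evaluate_counts(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0))
})

test_that("dice is symmetric and accuracy is the prevalence-weighted identity", {
  set.seed(7)
  for (k in 1:10) {
    d <- c(6, 8, 8)
    a <- array(runif(prod(d)) < 0.4, dim = d)
    b <- array(runif(prod(d)) < 0.4, dim = d)
    expect_identical(dice(a, b), dice(b, a))
    cts <- confusion(a, b)
    m <- evaluate_counts(cts)
    P <- cts$tp + cts$fn; N <- cts$tn + cts$fp
    expect_equal(m$accuracy, (P * m$sensitivity + N * m$specificity) / (P + N))
    expect_equal(m$dsc, dice(a, b))
  }
  expect_true(is.na(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2)))))
})
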
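# Evaluation metrics against formula arithmetic and brute-force oracles.

test_that("matched F1 follows the formula on constructed counts", {
  # 10 gt objects, 8 matched, 2 spurious predictions: TP 8, FP 2, FN 2
  d <- c(6, 40, 40)
  gt <- array(0L, d)
  seg <- array(0L, d)
  for (i in 1:10) {
    y <- 4 * i - 2
    gt[2:4, y:(y + 2), 5:7] <- i
    if (i <= 8) seg[2:4, y:(y + 2), 5:7] <- i  # perfect match
  }
  seg[2:4, 2:4, 30:32] <- 11L  # FP
  seg[2:4, 10:12, 30:32] <- 12L  # FP
  mr <- matched_f1(seg, gt)
  expect_identical(c(mr$tp, mr$fp, mr$fn), c(8L, 2L, 2L))
  expect_equal(mr$f1, 0.8)

  # identity
  mid <- matched_f1(gt, gt)
  expect_equal(mid$f1, 1)
  expect_identical(mid$fp + mid$fn, 0L)
})

test_that("matched F1 and best dice agree with brute force on random fixtures", {
  for (trial in 1:20) {
    gt <- random_label_fixture(c(32, 32, 32), n_obj = 4, seed = trial)
    seg <- random_label_fixture(c(32, 32, 32), n_obj = 4, seed = trial + 100)
    expect_equal(matched_f1(seg, gt)$f1, brute_force_f1(seg, gt),
                 tolerance = 1e-12)
    expect_equal(best_dice(seg, gt), brute_force_best_dice(seg, gt),
                 tolerance = 1e-12)
  }
})

test_that("F1 and Dice are symmetric; best dice is directional", {
  gt <- random_label_fixture(c(24, 24, 24), 3, seed = 5)
  seg <- random_label_fixture(c(24, 24, 24), 3, seed = 50)
  expect_equal(matched_f1(seg, gt)$f1, matched_f1(gt, seg)$f1)
  expect_equal(dice_score(seg, gt), dice_score(gt, seg))
  sym <- best_dice(seg, gt, symmetric = TRUE)
  expect_equal(sym, min(best_dice(seg, gt), best_dice(gt, seg)))
  expect_equal(best_dice(gt, gt, symmetric = TRUE), best_dice(gt, gt))
})

test_that("dice score arithmetic and edge cases", {
  a <- array(0L, c(4, 4))
  b <- array(0L, c(4, 4))
  a[1, 1:4] <- 1L
  b[1, 3:4] <- 1L
  b[2, 1:2] <- 1L
  expect_equal(dice_score(a, b), 0.5)  # |s|=|a|=4, overlap 2
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, array(0L, c(4, 4))), 0)
  expect_equal(dice_score(array(0L, c(4, 4)), array(0L, c(4, 4))), 1)
  expect_error(dice_score(a, array(0L, c(5, 5))), "shapes")
})

test_that("best dice of an object split in half is 2/3", {
  gt <- array(0L, c(4, 8, 8))
  gt[2:3, 2:5, 2:5] <- 1L          # 2*4*4 = 32 = 2N voxels
  seg <- array(0L, c(4, 8, 8))
  seg[2:3, 2:3, 2:5] <- 1L          # first half
  seg[2:3, 4:5, 2:5] <- 2L          # second half
  expect_equal(best_dice(seg, gt), 2 / 3)
  expect_equal(best_dice(gt, gt), 1)
})

test_that("surface dice on slabs: identity, displacement decay, empties", {
  d <- c(12, 24, 24)
  slab_at <- function(z) {
    m <- array(0L, d)
    m[z:(z + 1), 3:22, 3:22] <- 1L
    m
  }
  gt <- slab_at(4)
  expect_equal(surface_dice(gt, gt, tolerance = 1), 1)
  expect_equal(surface_dice(array(0L, d), gt), 0)
  expect_equal(surface_dice(array(0L, d), array(0L, d)), 1)
  # non-increasing with displacement, zero beyond tolerance
  scores <- vapply(0:4, function(off)
    surface_dice(slab_at(4 + off), gt, tolerance = 1), 1.0)
  expect_true(all(diff(scores) <= 1e-12))
  expect_equal(scores[1], 1)
  expect_equal(scores[4], 0)  # 3-voxel shift, 1-voxel tolerance
})

test_that("score aggregation reports SD only for five or more items", {
  a <- aggregate_scores(c(0.8, 0.9, 1, 0.7, 0.6))
  expect_false(is.na(a$sd))
  b <- aggregate_scores(c(0.8, 0.9))
  expect_true(is.na(b$sd))
  expect_equal(b$mean, 0.85)
})
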
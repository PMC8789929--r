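test_that("Dice handles the standard hand cases and conventions", {
  a <- array(0L, c(4, 4, 4)); b <- a
  a[1:2, 1:2, 1:2] <- 1L; b[1:2, 1:2, 1:2] <- 1L
  expect_equal(dice_coefficient(a, b, 1), 1)
  b2 <- array(0L, c(4, 4, 4)); b2[3:4, 3:4, 3:4] <- 1L
  expect_equal(dice_coefficient(a, b2, 1), 0)
  # |A| = |B| = 8 with |A n B| = 4
  b3 <- array(0L, c(4, 4, 4)); b3[1:2, 1:2, 2:3] <- 1L
  expect_equal(dice_coefficient(a, b3, 1), 0.5)
  # both-empty => 1 ; one-empty => 0
  empty <- array(0L, c(4, 4, 4))
  expect_equal(dice_coefficient(empty, empty, 2), 1)
  expect_equal(dice_coefficient(a, empty, 1), 0)
  expect_error(dice_coefficient(a, array(0L, c(3, 3, 3)), 1), "mismatch")
})

test_that("Dice is symmetric and matches the voxel-counting oracle", {
  set.seed(4)
  for (rep in 1:10) {
    a <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
    b <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
    for (l in 0:3) {
      expect_equal(dice_coefficient(a, b, l), dice_coefficient(b, a, l))
      expect_equal(dice_coefficient(a, b, l), oracle_dice(a, b, l))
    }
  }
})

test_that("Dice reports cover structures, average and whole-structure union", {
  set.seed(5)
  truth <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
  r <- dice_report(truth, truth)
  expect_identical(r$structure, c("label1", "label2", "label3", "average", "whole"))
  expect_true(all(r$dice == 1))
  # swapping two labels zeroes their Dice but keeps the union intact
  swapped <- truth
  swapped[truth == 1L] <- 2L; swapped[truth == 2L] <- 1L
  r2 <- dice_report(swapped, truth)
  expect_equal(r2$dice[r2$structure == "whole"], 1)
  expect_lt(r2$dice[r2$structure == "label1"], 0.5)
  # matches an explicit brute-force computation
  pred <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
  r3 <- dice_report(pred, truth)
  for (l in 1:3)
    expect_equal(r3$dice[r3$structure == paste0("label", l)],
                 oracle_dice(pred, truth, l))
  expect_equal(r3$dice[r3$structure == "average"],
               mean(r3$dice[1:3]))
})

test_that("fold plans are disjoint, exhaustive, deterministic and sized to protocol", {
  ids50 <- sprintf("s%02d", 1:50)
  plan <- make_folds(ids50, K = 5, seed = 2)
  counts <- table(plan$fold, plan$role)
  expect_true(all(counts[, "test"] == 10))
  expect_true(all(counts[, "train"] == 35))
  expect_true(all(counts[, "validation"] == 5))
  # each sample tests exactly once
  tested <- plan$sample_id[plan$role == "test"]
  expect_setequal(tested, ids50)
  expect_identical(anyDuplicated(tested), 0L)
  # within a fold, roles partition the full id set
  f1 <- plan[plan$fold == 1, ]
  expect_setequal(f1$sample_id, ids50)

  ids10 <- sprintf("w%02d", 1:10)
  plan10 <- make_folds(ids10, K = 5, seed = 2)
  counts10 <- table(plan10$fold, plan10$role)
  expect_true(all(counts10[, "test"] == 2))
  expect_true(all(counts10[, "train"] == 6))
  expect_true(all(counts10[, "validation"] == 2))

  expect_identical(make_folds(ids50, K = 5, seed = 9),
                   make_folds(ids50, K = 5, seed = 9))
  expect_error(make_folds(ids10, K = 11), "folds")
  expect_error(make_folds(c("a", "a", "b"), K = 2), "unique")
})

test_that("fold plans serialize to JSON", {
  plan <- make_folds(letters[1:10], K = 5, seed = 1)
  path <- tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$K, 5)
  expect_length(back$folds, 5)
})

test_that("report aggregation produces mean and sd per structure", {
  t1 <- array(sample(0:2, 4^3, TRUE), c(4, 4, 4))
  reps <- list(a = dice_report(t1, t1),
               b = dice_report(array(0L, c(4, 4, 4)), t1))
  agg <- aggregate_dice(reps)
  expect_identical(sort(unique(agg$structure)),
                   sort(unique(reps$a$structure)))
  avg <- agg[agg$structure == "average", ]
  expect_equal(avg$n, 2L)
  expect_equal(avg$mean, mean(c(1, reps$b$dice[reps$b$structure == "average"])))
})
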
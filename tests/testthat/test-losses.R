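test_that("losses reproduce hand-computed values on the 2x2 instance", {
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  t <- rbind(c(1, 0), c(0, 1))
  expect_equal(dice_loss(p, t), 1 - (0.8 / 2.2 + 0.6 / 1.8), tolerance = 1e-4)
  expect_equal(generalized_dice_loss(p, t), 1 - 2 * (0.8 + 0.6) / (2.2 + 1.8),
               tolerance = 1e-4)
  expect_equal(jaccard_loss(p, t), 1 - 0.5 * (0.8 / 1.4 + 0.6 / 1.2),
               tolerance = 1e-4)
  expect_equal(generalized_jaccard_loss(p, t), 1 - 1.4 / (1.4 + 1.2),
               tolerance = 1e-4)
  expect_equal(categorical_cross_entropy(p, t), -0.5 * (log(0.8) + log(0.6)),
               tolerance = 1e-6)
})

test_that("perfect and maximally wrong predictions hit the loss extremes", {
  set.seed(7)
  for (nc in 2:5) {
    n <- 40
    t <- diag(nc)[sample(nc, n, replace = TRUE), ]
    expect_lt(dice_loss(t, t), 1e-3)
    expect_lt(generalized_dice_loss(t, t), 1e-3)
    expect_lt(jaccard_loss(t, t), 1e-3)
    expect_lt(generalized_jaccard_loss(t, t), 1e-3)
    expect_lt(categorical_cross_entropy(t, t), 1e-5)
    # one-hot prediction disagreeing everywhere
    wrong <- t[, c(2:nc, 1)]
    expect_equal(dice_loss(wrong, t), 1, tolerance = 1e-3)
  }
})

test_that("the pooled-ratio Jaccard variant floors at 1 - 1/NC", {
  set.seed(8)
  for (nc in 2:5) {
    t <- diag(nc)[sample(nc, 30, replace = TRUE), ]
    expect_equal(jaccard_loss(t, t, literal = TRUE), 1 - 1 / nc,
                 tolerance = 1e-4)
  }
})

test_that("uniform CCE equals log NC and class weights follow their schemes", {
  t <- diag(4)[sample(4, 20, replace = TRUE), ]
  p <- matrix(1 / 4, 20, 4)
  expect_equal(categorical_cross_entropy(p, t), log(4), tolerance = 1e-8)

  t2 <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
              matrix(rep(c(0, 1), 2), ncol = 2, byrow = TRUE))
  expect_equal(as.vector(class_weights(t2, "inverse-volume")), c(0.1, 0.5))
  expect_equal(as.vector(class_weights(t2, "quadratic-inverse-volume")),
               c(0.01, 0.25))
  t3 <- cbind(rep(1, 4), rep(0, 4))
  expect_warning(w <- class_weights(t3, "inverse-volume"), "absent")
  expect_equal(as.vector(w), c(0.25, 0))
})

test_that("vectorized losses match the literal voxel-loop oracles", {
  set.seed(123)
  for (rep in 1:60) {
    inst <- random_instance(absent = rep %% 5 == 0)
    expect_equal(dice_loss(inst$p, inst$t), oracle_dl(inst$p, inst$t),
                 tolerance = 1e-6)
    expect_equal(generalized_dice_loss(inst$p, inst$t),
                 oracle_gdl(inst$p, inst$t), tolerance = 1e-6)
    expect_equal(jaccard_loss(inst$p, inst$t), oracle_jl(inst$p, inst$t),
                 tolerance = 1e-6)
    expect_equal(generalized_jaccard_loss(inst$p, inst$t),
                 oracle_gjl(inst$p, inst$t), tolerance = 1e-6)
    expect_equal(categorical_cross_entropy(inst$p, inst$t),
                 oracle_cce(inst$p, inst$t), tolerance = 1e-6)
  }
})

test_that("losses are invariant to voxel and class permutations", {
  set.seed(11)
  fns <- list(dice_loss, generalized_dice_loss, jaccard_loss,
              generalized_jaccard_loss, categorical_cross_entropy)
  for (rep in 1:10) {
    inst <- random_instance()
    pv <- sample(inst$n); pc <- sample(inst$nc)
    for (fn in fns) {
      base <- fn(inst$p, inst$t)
      expect_equal(fn(inst$p[pv, , drop = FALSE], inst$t[pv, , drop = FALSE]),
                   base, tolerance = 1e-10)
      expect_equal(fn(inst$p[, pc, drop = FALSE], inst$t[, pc, drop = FALSE]),
                   base, tolerance = 1e-10)
    }
  }
})

test_that("uniform weights collapse the generalized losses to pooled forms", {
  set.seed(21)
  for (rep in 1:10) {
    inst <- random_instance()
    p <- inst$p; t <- inst$t
    inter <- colSums(p * t)
    uni <- colSums(p) + colSums(t) - inter
    w1 <- rep(1, inst$nc)
    expect_equal(generalized_jaccard_loss(p, t, weights = w1),
                 1 - sum(inter) / (sum(uni) + 1e-5), tolerance = 1e-8)
    expect_equal(generalized_dice_loss(p, t, weights = w1),
                 1 - 2 * sum(inter) / (sum(colSums(p) + colSums(t)) + 1e-5),
                 tolerance = 1e-8)
    # weight scale invariance of GDL (ratio of homogeneous sums)
    expect_equal(generalized_dice_loss(p, t, weights = 2 * w1),
                 generalized_dice_loss(p, t, weights = w1), tolerance = 1e-5)
  }
})

test_that("equal class volumes make GJL coincide with the pooled Jaccard", {
  set.seed(31)
  nc <- 3; n <- 30   # balanced: 10 voxels per class
  t <- diag(nc)[rep(1:nc, each = n / nc), ]
  p <- matrix(runif(n * nc), n, nc); p <- p / rowSums(p)
  inter <- colSums(p * t); uni <- colSums(p) + colSums(t) - inter
  pooled <- 1 - sum(inter) / sum(uni)
  expect_equal(generalized_jaccard_loss(p, t), pooled, tolerance = 1e-4)
})

test_that("the multiscale composite weights scales as configured", {
  expect_equal(multiscale_loss(c(1, 1, 1)), 1)
  expect_equal(multiscale_loss(c(0, 0, 0.5)), 0.35)
  expect_error(multiscale_loss(c(1, 1, 1), weights = c(-0.1, 0.2, 0.9)),
               "nonnegative")
  expect_error(multiscale_loss(c(1, 1), weights = c(0.1, 0.2, 0.7)), "weight")
})

test_that("shape mismatches are rejected", {
  p <- matrix(0.5, 4, 2)
  t <- matrix(0.5, 3, 2)
  expect_error(dice_loss(p, t), "mismatch")
  expect_error(categorical_cross_entropy(p, t), "mismatch")
})
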
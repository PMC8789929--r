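# 6-connectivity check via breadth-first flood fill from one seed voxel.
is_six_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  visited <- array(FALSE, dim(mask))
  queue <- matrix(idx[1, ], ncol = 3)
  visited[queue] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  d <- dim(mask)
  while (nrow(queue) > 0) {
    nxt <- list()
    for (s in seq_len(6)) {
      cand <- sweep(queue, 2, shifts[s, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand)) {
        keep <- mask[cand] & !visited[cand]
        cand <- cand[keep, , drop = FALSE]
        if (nrow(cand)) {
          visited[cand] <- TRUE
          nxt[[length(nxt) + 1]] <- cand
        }
      }
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else matrix(0, 0, 3)
  }
  sum(visited) == sum(mask)
}

test_that("phantoms carry every configured label in a nested connected geometry", {
  for (ns in c(3L, 5L)) {
    cfg <- phantom_config(n_subfields = ns, seed = ns)
    s <- generate_phantom(cfg)
    expect_setequal(sort(unique(as.vector(s$labels))), 0:ns)
    for (k in seq_len(ns))
      expect_true(is_six_connected(s$labels == k))
    # nesting: shell k+1 voxels lie farther from the core than shell k on
    # average (layered structure)
  }
})

test_that("noise-free, bias-free phantoms are piecewise constant at the configured means", {
  cfg <- small_phantom_config(noise_sd = 0, bias_amplitude = 0, seed = 2)
  s <- generate_phantom(cfg)
  for (k in 0:cfg$n_subfields) {
    in_k <- s$labels == k
    expect_lt(max(abs(s$image[, , , 1][in_k] - cfg$t1_means[k + 1])), 1e-12)
    expect_lt(max(abs(s$image[, , , 2][in_k] - cfg$t2_means[k + 1])), 1e-12)
  }
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  cfg <- small_phantom_config(seed = 42)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  s3 <- generate_phantom(cfg, seed_offset = 1)
  expect_false(identical(s1$image, s3$image))
})

test_that("observed shell volumes match the analytic shape model within 15%", {
  cfg <- phantom_config(geometry_jitter = 0, seed = 6)
  s <- generate_phantom(cfg)
  obs <- as.numeric(table(factor(s$labels, levels = 0:cfg$n_subfields)))[-1]
  ana <- hippunet:::phantom_analytic_volumes(s$meta, cfg$n_subfields)
  expect_true(all(abs(obs / ana - 1) < 0.15))
})

test_that("mirrored bilateral pairs are exact reflections", {
  cfg <- small_phantom_config(bilateral = TRUE, seed = 8)
  pr <- generate_phantom(cfg)
  expect_identical(hippunet:::flip_lr(pr$left$image), pr$right$image)
  expect_identical(hippunet:::flip_lr(pr$left$labels), pr$right$labels)
  expect_identical(pr$left$side, "left")
})

test_that("layers too thin for the grid are rejected", {
  expect_error(phantom_config(grid = c(16, 16, 16), n_subfields = 5),
               "thinner")
})

test_that("degradations behave as specified", {
  cfg <- small_phantom_config(seed = 10)
  s <- generate_phantom(cfg)
  # zero magnitude is the identity for every kind
  for (kind in c("scale-shift", "blur", "extra-noise"))
    expect_identical(degrade_volume(s, kind, magnitude = 0)$image, s$image)
  # explicit affine corruption is exact
  d <- degrade_volume(s, "scale-shift", scale = 1.5, shift = 10)
  expect_equal(d$image, 1.5 * s$image + 10, tolerance = 1e-12)
  expect_identical(d$labels, s$labels)
  # blurring strictly reduces energy above the cutoff frequency
  line0 <- s$image[, 12, 20, 1]
  b <- degrade_volume(s, "blur", magnitude = 1)
  line1 <- b$image[, 12, 20, 1]
  sp0 <- Mod(fft(line0))^2; sp1 <- Mod(fft(line1))^2
  hi <- seq(9, 24)   # upper half of the spectrum (32-point fft)
  expect_lt(sum(sp1[hi]), sum(sp0[hi]))
  # extra noise is seeded and reproducible
  n1 <- degrade_volume(s, "extra-noise", magnitude = 0.2, seed = 5)
  n2 <- degrade_volume(s, "extra-noise", magnitude = 0.2, seed = 5)
  expect_identical(n1$image, n2$image)
})
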
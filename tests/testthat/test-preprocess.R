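test_that("z-score normalization has the definition's properties", {
  set.seed(1)
  x <- array(runif(10 * 10 * 10, 50, 150), c(10, 10, 10))
  z <- zscore_normalize(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-6)
  # affine invariance for positive scale
  expect_equal(zscore_normalize(3.7 * x + 12), z, tolerance = 1e-10)
  # two-voxel hand case
  expect_equal(as.vector(zscore_normalize(array(c(0, 2), c(2, 1, 1)))),
               c(-1, 1), tolerance = 1e-12)
  expect_error(zscore_normalize(array(5, c(4, 4, 4))), "zero intensity variance")
})

test_that("cropping is invertible and respects bounds", {
  set.seed(2)
  x <- array(rnorm(16 * 12 * 16), c(16, 12, 16))
  box <- crop_box(c(2, 10), c(0, 8), c(4, 12))
  cr <- crop_volume(x, box)
  expect_equal(dim(cr), c(8, 8, 8))
  expect_equal(cr[1, 1, 1], x[3, 1, 5])   # 0-based half-open convention
  full <- array(0, dim(x))
  back <- uncrop_volume(cr, full)
  expect_equal(back[3:10, 1:8, 5:12], x[3:10, 1:8, 5:12])
  # full-volume box is the identity
  all_box <- crop_box(c(0, 16), c(0, 12), c(0, 16))
  expect_equal(as.vector(crop_volume(x, all_box)), as.vector(x))
  expect_error(crop_volume(x, crop_box(c(0, 20), c(0, 8), c(0, 8))), "bounds")
})

test_that("a left-side crop of a bilateral phantom contains only left labels", {
  cfg <- small_phantom_config(bilateral = TRUE, seed = 9)
  pr <- generate_phantom(cfg)
  X <- dim(pr$right$labels)[1]
  full <- array(0L, c(2 * X, dim(pr$right$labels)[2:3]))
  full[1:X, , ] <- pr$left$labels
  full[(X + 1):(2 * X), , ] <- pr$right$labels
  left_box <- crop_box(c(0, X), c(0, dim(full)[2]), c(0, dim(full)[3]),
                       side = "left")
  lc <- crop_volume(full, left_box)
  expect_identical(array(lc, dim(pr$left$labels)), pr$left$labels)
  expect_gt(sum(lc > 0), 0)
  expect_identical(sum(lc > 0), sum(pr$left$labels > 0))
})

test_that("decimation plus B-spline upsampling has sampling-theory behaviour", {
  # constant volumes are unchanged
  expect_lt(max(abs(downsample_upsample(array(3, c(8, 8, 8)), 2) - 3)), 1e-5)
  # surviving coarse-grid samples are reproduced exactly (interpolation)
  set.seed(3)
  a <- array(rnorm(16^3), c(16, 16, 16))
  u <- downsample_upsample(a, 2)
  keep <- seq(1, 16, 2)
  expect_lt(max(abs(u[keep, keep, keep] - a[keep, keep, keep])), 1e-8)
  # a low-frequency wave below the coarse Nyquist limit is recovered
  n <- 48; f <- 1 / 32
  x <- array(0, c(n, n, n))
  for (i in 1:n) x[i, , ] <- cos(2 * pi * f * (i - 1))
  y <- downsample_upsample(x, 2)
  expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.02)
  # a sharp edge comes back blurred: the maximal gradient drops
  e <- array(0, c(16, 16, 16)); e[9:16, , ] <- 1
  eu <- downsample_upsample(e, 2)
  expect_lt(max(abs(diff(eu[, 8, 8]))), max(abs(diff(e[, 8, 8]))))
})

test_that("volumes round-trip through NIfTI with geometry intact", {
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(arr, path, spacing = c(0.5, 0.5, 0.5))
  back <- read_volume(path)
  expect_equal(unclass(back), arr, ignore_attr = TRUE)
  expect_equal(unname(RNifti::pixdim(back)), c(0.5, 0.5, 0.5))
  # writing again preserves the affine to numerical precision
  path2 <- tempfile(fileext = ".nii.gz")
  write_volume(unclass(back), path2, template = back)
  expect_lt(max(abs(RNifti::xform(read_volume(path2)) - RNifti::xform(back))),
            1e-6)
})

test_that("a crop origin shifts the stored NIfTI affine", {
  x <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  cr <- crop_volume(x, crop_box(c(4, 12), c(2, 10), c(6, 14)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(cr, path, spacing = c(0.5, 0.5, 0.5))
  xf <- RNifti::xform(read_volume(path))
  # translation moves by origin * (axis direction * spacing)
  expect_equal(abs(as.vector(xf[1:3, 4])), c(4, 2, 6) * 0.5, tolerance = 1e-5)
})

test_that("external steps run in canonical order with provenance, or pass through", {
  noop <- run_external_steps(c("a.nii", "b.nii"), external_steps_config())
  expect_identical(noop$paths, c("a.nii", "b.nii"))
  expect_identical(nrow(noop$provenance), 0L)

  src <- tempfile(fileext = ".txt"); writeLines("payload", src)
  cfg <- external_steps_config(denoise = "cp {input} {output}",
                               bias = "cp {input} {output}",
                               affine = "cp {input} {output}")
  res <- run_external_steps(src, cfg)
  expect_identical(nrow(res$provenance), 3L)
  expect_identical(res$provenance$step, c("denoise", "bias", "affine"))
  expect_identical(readLines(res$paths), "payload")

  disordered <- structure(list(bias = "cp {input} {output}",
                               denoise = "cp {input} {output}"),
                          class = "external_steps_config")
  expect_warning(res2 <- run_external_steps(src, disordered), "canonical order")
  expect_identical(res2$provenance$step, c("denoise", "bias"))

  broken <- external_steps_config(denoise = "false {input} {output}")
  expect_error(suppressWarnings(run_external_steps(src, broken)), "denoise")
})
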
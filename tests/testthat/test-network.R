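test_that("parameter counts match closed-form hand sums on tiny specs", {
  # one conv block straight from the input plus a 1x1x1 head
  spec <- network_spec(in_channels = 2, n_classes = 2, levels = 1,
                       base_filters = 4, blocks_per_level = 1,
                       deep_supervision = FALSE)
  # conv 2->4: 27*2*4 + 4 = 220 ; head 4->2: 4*2 + 2 = 10 ; no normalization
  expect_identical(count_parameters(spec), 230L)
  expect_identical(count_parameters(spec, include_stats = FALSE), 230L)

  # a single 3x3x3 convolution from 2 to 64 channels costs 2*64*27 + 64
  audit <- parameter_audit(network_spec())
  first_conv <- audit[audit$layer == "enc1b1.conv", ]
  expect_identical(first_conv$n_kernel + first_conv$n_bias, 2L * 64L * 27L + 64L)
})

test_that("parameter count is a pure function of the spec and scales as expected", {
  s1 <- tiny_spec(base_filters = 4)
  s2 <- tiny_spec(base_filters = 8)
  a1 <- parameter_audit(s1); a2 <- parameter_audit(s2)
  # convolution kernels quadruple when base filters double, except the
  # input and head layers which only double
  interior <- function(a) sum(a$n_kernel[a$kind == "conv3x3x3" &
                                           a$in_ch > s1$in_channels])
  expect_identical(interior(a2), 4L * interior(a1))
  net <- build_ds_unet3d(s1, seed = 1)
  expect_identical(count_parameters(net), count_parameters(s1))
  expect_identical(count_parameters(s1),
                   sum(vapply(net$params, length, integer(1))) +
                     sum(vapply(net$buffers, length, integer(1))))
})

test_that("deep supervision produces three probability heads at nested scales", {
  spec <- network_spec(in_channels = 2, n_classes = 3, levels = 4,
                       base_filters = 2, blocks_per_level = 1, dropout_rate = 0)
  net <- build_ds_unet3d(spec, seed = 2)
  x <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16, 2))
  fwd <- net_forward(net, x)
  expect_named(fwd$probs, c("high", "medium", "low"))
  expect_equal(dim(fwd$probs$high)[1:3], c(16, 16, 16))
  expect_equal(dim(fwd$probs$medium)[1:3], c(8, 8, 8))
  expect_equal(dim(fwd$probs$low)[1:3], c(4, 4, 4))
  for (p in fwd$probs) {
    rs <- rowSums(matrix(p, ncol = 3))
    expect_lt(max(abs(rs - 1)), 1e-5)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("disabling deep supervision yields the classic single-head U-Net", {
  spec <- tiny_spec(deep_supervision = FALSE)
  net <- build_ds_unet3d(spec, seed = 2)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  fwd <- net_forward(net, x)
  expect_named(fwd$probs, "high")
  audit <- parameter_audit(spec)
  expect_identical(sum(audit$kind == "conv1x1x1"), 1L)
})

test_that("forward passes are deterministic and finite on degenerate input", {
  spec <- tiny_spec()
  net <- build_ds_unet3d(spec, seed = 5)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  f1 <- net_forward(net, x)
  f2 <- net_forward(net, x)
  expect_identical(f1$probs, f2$probs)
  zeros <- array(0, c(8, 8, 8, 2))
  fz <- net_forward(net, zeros)
  expect_true(all(is.finite(fz$probs$high)))
})

test_that("indivisible spatial dimensions are rejected with the axis named", {
  spec <- network_spec(levels = 3, base_filters = 2, blocks_per_level = 1)
  net <- build_ds_unet3d(spec, seed = 1)
  x <- array(0, c(8, 6, 8, 2))
  expect_error(net_forward(net, x), "Y")
})

test_that("feedback wiring changes outputs but concat alone adds parameters", {
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  specs <- lapply(c("additive", "concat", "none"), function(fb)
    tiny_spec(levels = 3, blocks_per_level = 1, feedback = fb))
  counts <- vapply(specs, count_parameters, integer(1))
  expect_identical(counts[1], counts[3])     # additive feedback is free
  expect_gt(counts[2], counts[1])            # concat adds input channels
  nets <- lapply(specs, build_ds_unet3d, seed = 4)
  outs <- lapply(nets, function(n) net_forward(n, x)$probs$high)
  expect_gt(max(abs(outs[[1]] - outs[[3]])), 1e-8)
})

test_that("network specs round-trip through YAML", {
  spec <- tiny_spec(feedback = "concat", dropout_rate = 0.3)
  path <- tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(unclass(back), unclass(spec))
})
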
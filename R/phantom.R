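#' Synthetic two-channel hippocampus-like phantom configuration
#'
#' Describes the generative model for test phantoms: a curved tube (a
#' "banana" in the x-z plane) partitioned into `n_subfields` nested laminar
#' shells, mimicking the layered geometry of hippocampal subfields without
#' any claim of anatomical fidelity.  The two channels emulate T1-like and
#' T2-like contrasts through per-label mean intensities (distinct within
#' each channel, with opposed orderings across channels), modulated by a
#' smooth multiplicative bias field and additive Gaussian noise.
#'
#' The default grid of 48 x 32 x 48 voxels at a nominal 0.5 mm spacing is
#' small enough for CPU-scale training experiments while remaining
#' divisible through 3-4 resolution levels.  `n_subfields = 3` mirrors a
#' three-part labelling protocol (plus background); `n_subfields = 5` the
#' five-label protocol.
#'
#' @param grid integer 3-vector of voxel dimensions.
#' @param spacing voxel size in mm per axis.
#' @param n_subfields number of nested shell labels (3 or 5 typical).
#' @param t1_means,t2_means per-label mean intensities, background first
#'   (length `n_subfields + 1`); defaults interpolate opposed contrast
#'   ramps.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field.
#' @param tube_radius outer tube radius in voxels (default scaled to grid).
#' @param arc_radius centerline arc radius in voxels.
#' @param arc_span angular span of the arc in radians.
#' @param geometry_jitter relative jitter of the geometry per sample.
#' @param bilateral if `TRUE`, [generate_phantom()] returns a mirrored
#'   left/right pair.
#' @param seed integer seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(48L, 32L, 48L), spacing = c(0.5, 0.5, 0.5),
                           n_subfields = 3L,
                           t1_means = NULL, t2_means = NULL,
                           noise_sd = 0.1, bias_amplitude = 0.2,
                           tube_radius = 0.36 * min(grid[1], grid[3]) / 2,
                           arc_radius = 0.30 * min(grid[1], grid[3]),
                           arc_span = 2 * pi / 3,
                           geometry_jitter = 0.05,
                           bilateral = FALSE, seed = 1L) {
  n_subfields <- as.integer(n_subfields)
  stopifnot(n_subfields >= 1, noise_sd >= 0, bias_amplitude >= 0,
            length(grid) == 3)
  if (is.null(t1_means)) t1_means <- c(0.2, seq(0.5, 0.9, length.out = n_subfields))
  if (is.null(t2_means)) t2_means <- c(0.3, seq(0.9, 0.5, length.out = n_subfields))
  stopifnot(length(t1_means) == n_subfields + 1,
            length(t2_means) == n_subfields + 1,
            !anyDuplicated(t1_means), !anyDuplicated(t2_means))
  if (tube_radius / n_subfields < 1.5)
    stop("shell layers thinner than ~1.5 voxels; enlarge the grid or ",
         "reduce n_subfields")
  structure(list(grid = as.integer(grid), spacing = spacing,
                 n_subfields = n_subfields,
                 t1_means = t1_means, t2_means = t2_means,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 tube_radius = tube_radius, arc_radius = arc_radius,
                 arc_span = arc_span, geometry_jitter = geometry_jitter,
                 bilateral = bilateral, seed = as.integer(seed)),
            class = "phantom_config")
}

# Distance from every voxel to the arc centerline.  The arc lies in the
# x-z plane, centred at `center` = (cx, cz), radius `arc_radius`, spanning
# `arc_span` radians symmetric about the +x direction, at height `y_center`.
arc_distance <- function(grid, center, arc_radius, arc_span, y_center) {
  X <- grid[1]; Y <- grid[2]; Z <- grid[3]
  xs <- seq_len(X) - center[1]
  ys <- seq_len(Y) - y_center
  zs <- seq_len(Z) - center[2]
  x2 <- outer(xs, rep(1, Z))                                 # X x Z
  z2 <- outer(rep(1, X), zs)
  rho <- sqrt(x2^2 + z2^2)
  phi <- atan2(z2, x2)
  half <- arc_span / 2
  in_arc <- abs(phi) <= half
  d_arc <- abs(rho - arc_radius)
  ex1 <- arc_radius * cos(half); ez1 <- arc_radius * sin(half)
  d_end <- pmin(sqrt((x2 - ex1)^2 + (z2 - ez1)^2),
                sqrt((x2 - ex1)^2 + (z2 + ez1)^2))
  d_xz <- ifelse(in_arc, d_arc, d_end)
  out <- array(0, grid)
  for (j in seq_len(Y)) out[, j, ] <- sqrt(d_xz^2 + ys[j]^2)
  out
}

#' Generate a synthetic phantom
#'
#' Draws one phantom (or a mirrored left/right pair when the configuration
#' is bilateral): a curved-tube label map with nested shells (label 0 is
#' background, labels `1..n_subfields` the shells from the core outward)
#' and a two-channel image with per-label contrasts, smooth multiplicative
#' bias and Gaussian noise.  Generation is fully determined by
#' `cfg$seed` (plus `seed_offset`).
#'
#' @param cfg a [phantom_config()].
#' @param seed_offset added to the configured seed, for drawing sample
#'   collections.
#' @param subject optional subject identifier stored in the sample.
#' @return a `hippunet_sample` (list with `image` `(X,Y,Z,2)` array,
#'   `labels` integer 3D array, `spacing`, `side`, `subject`), or a list of
#'   two samples (right, left) in bilateral mode.
#' @export
generate_phantom <- function(cfg, seed_offset = 0L, subject = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  seed <- derive_seed(cfg$seed, seed_offset)
  sample <- with_seed(seed, {
    jit <- function(v) v * (1 + cfg$geometry_jitter * runif(1, -1, 1))
    arc_r <- jit(cfg$arc_radius)
    tube_r <- jit(cfg$tube_radius)
    grid <- cfg$grid
    center <- c(grid[1] / 2 - arc_r / 2, grid[3] / 2 + 0.5)
    y_center <- grid[2] / 2 + 0.5
    d <- arc_distance(grid, center, arc_r, cfg$arc_span, y_center)
    radii <- tube_r * seq_len(cfg$n_subfields) / cfg$n_subfields
    labels <- array(0L, grid)
    for (k in rev(seq_len(cfg$n_subfields))) labels[d <= radii[k]] <- k
    # smooth multiplicative bias: seeded random linear gradient
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    u <- seq_len(grid[1]) / grid[1] - 0.5
    v <- seq_len(grid[2]) / grid[2] - 0.5
    w <- seq_len(grid[3]) / grid[3] - 0.5
    gradfield <- outer(outer(u * dir[1], v * dir[2], "+"), w * dir[3], "+")
    bias <- 1 + cfg$bias_amplitude * gradfield
    img <- array(0, c(grid, 2L))
    means <- list(cfg$t1_means, cfg$t2_means)
    for (ch in 1:2) {
      base <- array(means[[ch]][labels + 1L], grid)
      img[, , , ch] <- base * bias + rnorm(length(base), sd = cfg$noise_sd)
    }
    list(image = img, labels = labels,
         meta = list(arc_radius = arc_r, tube_radius = tube_r,
                     arc_span = cfg$arc_span, radii = radii, seed = seed))
  })
  right <- structure(list(image = sample$image, labels = sample$labels,
                          spacing = cfg$spacing, side = "right",
                          subject = subject, meta = sample$meta),
                     class = "hippunet_sample")
  if (!cfg$bilateral) return(right)
  left <- right
  left$image <- flip_lr(right$image)
  left$labels <- flip_lr(right$labels)
  left$side <- "left"
  list(right = right, left = left)
}

#' Generate a collection of phantoms
#'
#' @param n number of subjects.
#' @param cfg a [phantom_config()].
#' @param seed overrides the configuration seed.
#' @return list of `hippunet_sample` objects (two per subject when
#'   bilateral, sides interleaved).
#' @export
generate_phantom_set <- function(n, cfg = phantom_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- list()
  for (i in seq_len(n)) {
    s <- generate_phantom(cfg, seed_offset = i, subject = sprintf("subj%03d", i))
    if (cfg$bilateral) out <- c(out, unname(s)) else out <- c(out, list(s))
  }
  out
}

# Analytic shell volumes (voxels^3) from the shape model: arc-swept annulus
# (Pappus) plus the spherical end caps.
phantom_analytic_volumes <- function(meta, n_subfields) {
  radii <- c(0, meta$radii)
  arc_len <- meta$arc_span * meta$arc_radius
  vapply(seq_len(n_subfields), function(k) {
    annulus <- pi * (radii[k + 1]^2 - radii[k]^2) * arc_len
    caps <- 4 / 3 * pi * (radii[k + 1]^3 - radii[k]^3)
    annulus + caps
  }, numeric(1))
}

flip_lr <- function(a) {
  d <- dim(a)
  if (length(d) == 3L) a[d[1]:1, , , drop = FALSE]
  else a[d[1]:1, , , , drop = FALSE]
}

#' Degrade a volume
#'
#' Controlled image-quality corruptions used to probe prediction
#' robustness: a global affine intensity `"scale-shift"`, Gaussian
#' `"blur"`, or `"extra-noise"`.  Labels are never touched.  With
#' `magnitude = 0` every kind is the identity.
#'
#' @param x a `hippunet_sample` or a bare image array.
#' @param kind corruption kind.
#' @param magnitude scalar strength: for `"scale-shift"`, the default scale
#'   is `1 + magnitude` (override with `scale`/`shift`); for `"blur"` the
#'   Gaussian sigma in voxels; for `"extra-noise"` the added noise sd.
#' @param scale,shift explicit affine coefficients for `"scale-shift"`.
#' @param seed seed for `"extra-noise"`.
#' @return the degraded object, same type as `x`.
#' @export
degrade_volume <- function(x, kind = c("scale-shift", "blur", "extra-noise"),
                           magnitude = 0, scale = NULL, shift = NULL,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0)
  img <- if (inherits(x, "hippunet_sample")) x$image else x
  out <- switch(kind,
    "scale-shift" = {
      a <- scale %||% (1 + magnitude)
      b <- shift %||% 0
      a * img + b
    },
    "blur" = if (magnitude == 0) img else gaussian_blur(img, magnitude),
    "extra-noise" = if (magnitude == 0) img else
      img + with_seed(derive_seed(seed, 97L),
                      array(rnorm(length(img), sd = magnitude), dim(img))))
  if (inherits(x, "hippunet_sample")) { x$image <- out; x } else out
}
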
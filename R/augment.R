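#' Augmentation configuration
#'
#' Parameters for the training-time augmentation suite: random smoothing
#' or sharpening (simulating lower/higher-quality acquisitions) and mixup
#' (convex combinations of sample pairs with a symmetric Beta mixing
#' coefficient).  Each augmentation is applied independently per sample
#' with the configured probability.
#'
#' @param mixup_alpha shape parameter of the symmetric `Beta(alpha, alpha)`
#'   mixing distribution (0.3 by default).
#' @param smooth_sigma_range range of Gaussian sigmas, in voxels.
#' @param sharpen_amount_range range of unsharp-masking amounts.
#' @param p_smooth_sharpen per-sample probability of the smooth/sharpen
#'   draw.
#' @param p_mixup per-sample probability of mixup.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(mixup_alpha = 0.3,
                           smooth_sigma_range = c(0.3, 1.2),
                           sharpen_amount_range = c(0.2, 1.0),
                           p_smooth_sharpen = 0.5, p_mixup = 0.5) {
  stopifnot(mixup_alpha > 0, length(smooth_sigma_range) == 2,
            length(sharpen_amount_range) == 2,
            diff(smooth_sigma_range) >= 0, diff(sharpen_amount_range) >= 0)
  structure(list(mixup_alpha = mixup_alpha,
                 smooth_sigma_range = smooth_sigma_range,
                 sharpen_amount_range = sharpen_amount_range,
                 p_smooth_sharpen = p_smooth_sharpen, p_mixup = p_mixup),
            class = "augment_config")
}

#' Pool left and right crops into a right-oriented set
#'
#' Doubles the effective training set of a bilateral structure: right-side
#' crops pass through unchanged and left-side crops are mirrored along the
#' left-right axis (first array dimension), images and labels identically,
#' so every output crop is right-oriented.
#'
#' @param samples list of `hippunet_sample` objects with a `side` tag
#'   (`"left"` or `"right"`).
#' @return list of right-oriented samples, same length as the input.
#' @export
flip_pool <- function(samples) {
  lapply(samples, function(s) {
    side <- s$side %||% stop("sample has no side tag")
    if (!side %in% c("left", "right"))
      stop("unknown side tag: ", side)
    if (side == "left") {
      s$image <- flip_lr(s$image)
      s$labels <- flip_lr(s$labels)
      s$side <- "right"
      s$flipped <- TRUE
    }
    s
  })
}

# Separable Gaussian blur of a 3D or 4D (multi-channel) array, sigma in
# voxels, with renormalized edge handling.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  .gaussian_blur3d(x, dim(x), sigma)
}

#' Randomly smooth or sharpen a sample
#'
#' With equal probability applies Gaussian smoothing (sigma drawn uniformly
#' from `smooth_sigma_range`) or unsharp masking (amount drawn from
#' `sharpen_amount_range`), the same operation with the same parameters to
#' both channels.  Labels are untouched.
#'
#' @param x a `hippunet_sample` or image array.
#' @param cfg an [augment_config()].
#' @param seed integer seed making the draw reproducible.
#' @return same type as `x`.
#' @export
smooth_sharpen <- function(x, cfg = augment_config(), seed = 1L) {
  img <- if (inherits(x, "hippunet_sample")) x$image else x
  out <- with_seed(derive_seed(seed, 11L), {
    if (runif(1) < 0.5) {
      sigma <- runif(1, cfg$smooth_sigma_range[1], cfg$smooth_sigma_range[2])
      gaussian_blur(img, sigma)
    } else {
      amount <- runif(1, cfg$sharpen_amount_range[1], cfg$sharpen_amount_range[2])
      img + amount * (img - gaussian_blur(img, 1))
    }
  })
  if (inherits(x, "hippunet_sample")) { x$image <- out; x } else out
}

#' Mixup of two samples
#'
#' Draws a mixing coefficient `lambda ~ Beta(alpha, alpha)` and returns the
#' convex combinations `lambda * a + (1 - lambda) * b` of both the images
#' and the (one-hot or soft) label fields.  The blended label rows remain
#' on the probability simplex.
#'
#' @param a,b lists with elements `image` (`(X,Y,Z,C)` array) and `target`
#'   (`(X,Y,Z,NC)` soft label array) on the same grid.
#' @param alpha Beta shape parameter.
#' @param seed integer seed; alternatively supply `lambda` directly.
#' @param lambda optional fixed mixing coefficient (bypasses the draw).
#' @return list with blended `image`, `target` and the `lambda` used.
#' @export
mixup <- function(a, b, alpha = 0.3, seed = 1L, lambda = NULL) {
  if (!identical(dim(a$image), dim(b$image)) ||
      !identical(dim(a$target), dim(b$target)))
    stop("mixup partners must share the same grid")
  lam <- lambda %||% with_seed(derive_seed(seed, 23L), rbeta(1, alpha, alpha))
  list(image = lam * a$image + (1 - lam) * b$image,
       target = lam * a$target + (1 - lam) * b$target,
       lambda = lam)
}
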
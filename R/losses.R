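#' Region-overlap training objectives
#'
#' Differentiable losses for multi-class volumetric segmentation, computed
#' from a predicted per-voxel class probability field `p` and a one-hot (or
#' soft, for mixup targets) reference field `t`.  Both arguments may be
#' `N x NC` matrices or arrays whose last dimension indexes the `NC` classes
#' (background included as class 1).  All overlap losses lie in `[0, 1]` up
#' to the smoothing constant and reach 0 exactly at a perfect prediction.
#'
#' `dice_loss()` is the per-class-mean soft Dice loss
#' \deqn{1 - \frac{2}{NC} \sum_c \frac{\sum_i p_{ci} t_{ci}}
#'   {\sum_i p_{ci} + t_{ci}}.}
#' `generalized_dice_loss()` pools classes with weights
#' \eqn{w_c = 1/(\sum_i t_{ci})^2} (squared inverse class volume),
#' `jaccard_loss()` is the per-class-mean soft Jaccard (intersection over
#' union) loss, and `generalized_jaccard_loss()` pools the Jaccard ratio
#' with linear inverse-volume weights \eqn{w_c = 1/\sum_i t_{ci}} — the
#' pooled-union weighting that this package treats as its reference
#' training objective.  `categorical_cross_entropy()` is the voxel-mean
#' cross-entropy with probability clipping.
#'
#' A smoothing constant `eps` is added to every denominator so that absent
#' classes cannot produce division by zero.  Classes with zero reference
#' volume are dropped from class means and receive zero pooling weight (see
#' [class_weights()]); with all classes absent the losses are 0 by
#' convention.
#'
#' @param p predicted probabilities, `N x NC` matrix or `(* , NC)` array;
#'   rows must sum to 1.
#' @param t reference probabilities of the same shape (one-hot for hard
#'   labels, arbitrary simplex rows for soft targets).
#' @param eps smoothing constant added to every denominator.
#' @param literal for `jaccard_loss()`: if `TRUE`, evaluate the pooled-ratio
#'   variant that scales a single pooled Jaccard ratio by `1/NC`.  That form
#'   cannot reach 0 at a perfect prediction (its floor is `1 - 1/NC`), so
#'   the per-class mean is the default.
#' @param weights optional per-class weights overriding the scheme the
#'   generalized losses use (a numeric vector of length `NC`).
#' @return a single numeric loss value.
#' @seealso [loss_gradient()] for the analytic gradients,
#'   [multiscale_loss()] for the deep-supervision composite.
#' @examples
#' p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
#' t <- rbind(c(1, 0), c(0, 1))
#' dice_loss(p, t)
#' generalized_jaccard_loss(p, t)
#' @export
dice_loss <- function(p, t, eps = 1e-5) {
  check_same_shape(p, t)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  vol <- colSums(t)
  keep <- vol > 0
  if (!any(keep)) return(0)
  num <- colSums(p * t)[keep]
  den <- (colSums(p) + vol)[keep] + eps
  1 - (2 / sum(keep)) * sum(num / den)
}

#' @rdname dice_loss
#' @export
generalized_dice_loss <- function(p, t, eps = 1e-5, weights = NULL) {
  check_same_shape(p, t)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  w <- weights %||% class_weights(t, "quadratic-inverse-volume", quiet = TRUE)
  num <- sum(w * colSums(p * t))
  den <- sum(w * (colSums(p) + colSums(t))) + eps
  if (den <= eps) return(0)
  1 - 2 * num / den
}

#' @rdname dice_loss
#' @export
jaccard_loss <- function(p, t, eps = 1e-5, literal = FALSE) {
  check_same_shape(p, t)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  inter <- colSums(p * t)
  union <- colSums(p) + colSums(t) - inter
  if (literal) {
    nc <- ncol(p)
    return(1 - (1 / nc) * sum(inter) / (sum(union) + eps))
  }
  keep <- colSums(t) > 0
  if (!any(keep)) return(0)
  1 - mean(inter[keep] / (union[keep] + eps))
}

#' @rdname dice_loss
#' @export
generalized_jaccard_loss <- function(p, t, eps = 1e-5, weights = NULL) {
  check_same_shape(p, t)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  w <- weights %||% class_weights(t, "inverse-volume", quiet = TRUE)
  inter <- colSums(p * t)
  union <- colSums(p) + colSums(t) - inter
  den <- sum(w * union) + eps
  if (den <= eps) return(0)
  1 - sum(w * inter) / den
}

#' @rdname dice_loss
#' @param clip probability clipping bound for the logarithm.
#' @export
categorical_cross_entropy <- function(p, t, clip = 1e-7) {
  check_same_shape(p, t)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(rowSums(t * log(p)))
}

#' Per-class volume weights
#'
#' Computes the class weights used by the generalized overlap losses from
#' the reference field's class volumes \eqn{V_c = \sum_i t_{ci}}:
#' `"quadratic-inverse-volume"` gives \eqn{1/V_c^2} (the classic
#' generalized Dice weighting), `"inverse-volume"` gives \eqn{1/V_c} (the
#' linear weighting of the generalized Jaccard loss), and `"uniform"` gives
#' 1 for every class.  Absent classes (zero volume) receive weight 0 and a
#' warning, so they drop out of both pooled sums instead of propagating
#' infinities.
#'
#' @param t reference field (`N x NC` matrix or `(*, NC)` array).
#' @param scheme weighting scheme.
#' @param quiet suppress the absent-class warning.
#' @return named numeric vector of length `NC` with attribute `scheme`.
#' @export
class_weights <- function(t,
                          scheme = c("inverse-volume", "quadratic-inverse-volume",
                                     "uniform"),
                          quiet = FALSE) {
  scheme <- match.arg(scheme)
  t <- as_class_matrix(t)
  vol <- colSums(t)
  w <- switch(scheme,
    "uniform" = rep(1, length(vol)),
    "inverse-volume" = ifelse(vol > 0, 1 / vol, 0),
    "quadratic-inverse-volume" = ifelse(vol > 0, 1 / vol^2, 0))
  if (!quiet && any(vol == 0))
    warning("absent class(es) ", paste(which(vol == 0), collapse = ", "),
            " assigned zero weight")
  names(w) <- paste0("class", seq_along(w) - 1L)
  attr(w, "scheme") <- scheme
  w
}

#' Deep-supervision composite loss
#'
#' Weighted sum of the per-scale losses produced by the network's
#' supervision heads.  The default weights `(0.1, 0.2, 0.7)` for the low,
#' medium and high-resolution outputs emphasise the full-resolution
#' segmentation while still propagating gradient to the coarse heads.
#'
#' @param losses numeric vector of per-scale losses ordered coarse to fine
#'   (low, medium, high).
#' @param weights nonnegative weights of the same length.
#' @return the scalar composite loss.
#' @export
multiscale_loss <- function(losses, weights = c(low = 0.1, medium = 0.2, high = 0.7)) {
  if (length(losses) != length(weights))
    stop("need one weight per scale (", length(losses), " losses, ",
         length(weights), " weights)")
  if (any(weights < 0)) stop("multiscale loss weights must be nonnegative")
  sum(weights * losses)
}

# Default multiscale weights for a network with `h` supervision heads:
# the finest `h` of (0.1, 0.2, 0.7), renormalized to sum to 1 so the loss
# scale is comparable across architectures.
default_scale_weights <- function(h) {
  base <- c(0.1, 0.2, 0.7)
  if (h > 3) stop("at most three supervision scales are supported")
  w <- tail(base, h)
  w / sum(w)
}

#' Analytic gradients of the overlap losses
#'
#' Returns \eqn{\partial L / \partial p} for the requested loss at `(p, t)`,
#' in the same shape as `p`.  These are the closed-form gradients used by
#' the training loop; they are validated against central finite differences
#' in the test suite.
#'
#' @inheritParams dice_loss
#' @param type one of `"dl"`, `"gdl"`, `"jl"`, `"gjl"`, `"cce"`.
#' @param clip clipping bound for `"cce"`.
#' @return matrix or array matching `p`.
#' @export
loss_gradient <- function(type, p, t, eps = 1e-5, clip = 1e-7) {
  type <- match.arg(type, c("dl", "gdl", "jl", "gjl", "cce"))
  check_same_shape(p, t)
  shape <- dim(p)
  p <- as_class_matrix(p); t <- as_class_matrix(t)
  n <- nrow(p); nc <- ncol(p)
  vol <- colSums(t)
  g <- switch(type,
    dl = {
      keep <- vol > 0
      num <- colSums(p * t); den <- colSums(p) + vol + eps
      k <- sum(keep)
      gm <- matrix(0, n, nc)
      if (k > 0) {
        # d/dp_ci [num_c/den_c] = (t_ci * den_c - num_c) / den_c^2
        a <- rep(1 / den^2, each = n); dim(a) <- c(n, nc)
        gm <- -(2 / k) * (t * rep(den, each = n) - rep(num, each = n)) / rep(den^2, each = n)
        gm[, !keep] <- 0
      }
      gm
    },
    gdl = {
      w <- class_weights(t, "quadratic-inverse-volume", quiet = TRUE)
      U <- sum(w * colSums(p * t))
      V <- sum(w * (colSums(p) + vol)) + eps
      if (V <= eps) matrix(0, n, nc)
      else -2 * (t * rep(w, each = n) * V - U * rep(w, each = n)) / V^2
    },
    jl = {
      keep <- vol > 0
      inter <- colSums(p * t)
      uni <- colSums(p) + vol - inter + eps
      k <- sum(keep)
      gm <- matrix(0, n, nc)
      if (k > 0) {
        # d inter/dp = t ; d union/dp = 1 - t
        gm <- -(1 / k) * (t * rep(uni, each = n) - rep(inter, each = n) * (1 - t)) /
          rep(uni^2, each = n)
        gm[, !keep] <- 0
      }
      gm
    },
    gjl = {
      w <- class_weights(t, "inverse-volume", quiet = TRUE)
      inter <- colSums(p * t)
      uni <- colSums(p) + vol - inter
      U <- sum(w * inter); V <- sum(w * uni) + eps
      if (V <= eps) matrix(0, n, nc)
      else {
        wrep <- rep(w, each = n); dim(wrep) <- c(n, nc)
        -(t * wrep * V - U * wrep * (1 - t)) / V^2
      }
    },
    cce = {
      pc <- pmin(pmax(p, clip), 1 - clip)
      gm <- -t / pc / n
      gm[p < clip | p > 1 - clip] <- 0
      gm
    })
  if (length(shape) > 2L) dim(g) <- shape
  g
}

# Resolve a loss name from the training configuration to (fn, grad).
resolve_loss <- function(name) {
  name <- match.arg(name, c("cce", "dl", "gdl", "jl", "gjl"))
  fn <- switch(name,
    cce = categorical_cross_entropy,
    dl  = dice_loss,
    gdl = generalized_dice_loss,
    jl  = jaccard_loss,
    gjl = generalized_jaccard_loss)
  list(name = name,
       value = fn,
       gradient = function(p, t) loss_gradient(name, p, t))
}
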
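# Internal helpers shared across modules.

# Row-wise softmax over the last (class) dimension of a 4D array or the
# columns of a matrix.  Subtracts the row max for numerical stability.
softmax <- function(z) {
  d <- dim(z)
  if (length(d) == 4L) {
    m <- matrix(z, ncol = d[4])
    p <- softmax(m)
    dim(p) <- d
    return(p)
  }
  mx <- z[, 1L]
  for (c in seq_len(ncol(z))[-1L]) mx <- pmax(mx, z[, c])
  e <- exp(z - mx)
  e / rowSums(e)
}

# Backward pass of row-wise softmax: given dL/dp and p, return dL/dz.
softmax_backward <- function(gp, p) {
  d <- dim(p)
  if (length(d) == 4L) {
    gp <- matrix(gp, ncol = d[4]); pm <- matrix(p, ncol = d[4])
    gz <- pm * (gp - rowSums(gp * pm))
    dim(gz) <- d
    return(gz)
  }
  p * (gp - rowSums(gp * p))
}

#' One-hot encode a label volume
#'
#' Expands an integer 3D label map (values `0..n_classes-1`) into an
#' `(X, Y, Z, n_classes)` indicator array, the soft-label representation
#' used as a network target and by mixup.
#'
#' @param labels integer 3D array.
#' @param n_classes number of classes including background.
#' @return 4D array of 0/1 indicators, one 1 per voxel.
#' @export
one_hot_volume <- function(labels, n_classes) {
  d <- dim(labels)
  stopifnot(length(d) == 3L)
  out <- array(0, c(d, n_classes))
  n <- prod(d)
  idx <- seq_len(n) + n * as.integer(labels)
  out[idx] <- 1
  out
}

# Coerce a probability/label container (matrix N x NC or array ... x NC)
# to an N x NC matrix.
as_class_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array with a class dimension")
  if (length(d) == 2L) return(as.matrix(x))
  matrix(x, ncol = d[length(d)])
}

check_same_shape <- function(p, t) {
  if (!identical(dim(p), dim(t)))
    stop("probability and target containers have mismatched dimensions (",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t), collapse = "x"), ")")
}

# Deterministic derived seeds, kept within the 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt * 7919) %% 2147483647)
}

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
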
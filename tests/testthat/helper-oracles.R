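# Literal voxel-by-voxel loss oracles: double loops transcribing the loss
# definitions term by term, kept deliberately independent of the package's
# vectorized implementations.  Absent classes (zero reference volume) are
# excluded from per-class means and weighted sums, mirroring the documented
# convention.

oracle_dl <- function(p, t, eps = 1e-5) {
  N <- nrow(p); NC <- ncol(p)
  present <- which(colSums(t) > 0)
  if (!length(present)) return(0)
  acc <- 0
  for (c in present) {
    num <- 0; den <- 0
    for (i in seq_len(N)) {
      num <- num + p[i, c] * t[i, c]
      den <- den + p[i, c] + t[i, c]
    }
    acc <- acc + num / (den + eps)
  }
  1 - (2 / length(present)) * acc
}

oracle_gdl <- function(p, t, eps = 1e-5) {
  N <- nrow(p); NC <- ncol(p)
  num <- 0; den <- 0
  for (c in seq_len(NC)) {
    v <- sum(t[, c])
    if (v == 0) next
    w <- 1 / v^2
    sn <- 0; sd_ <- 0
    for (i in seq_len(N)) {
      sn <- sn + p[i, c] * t[i, c]
      sd_ <- sd_ + p[i, c] + t[i, c]
    }
    num <- num + w * sn
    den <- den + w * sd_
  }
  if (den == 0) return(0)
  1 - 2 * num / (den + eps)
}

oracle_jl <- function(p, t, eps = 1e-5) {
  N <- nrow(p); NC <- ncol(p)
  present <- which(colSums(t) > 0)
  if (!length(present)) return(0)
  acc <- 0
  for (c in present) {
    inter <- 0; tot <- 0
    for (i in seq_len(N)) {
      inter <- inter + p[i, c] * t[i, c]
      tot <- tot + p[i, c] + t[i, c]
    }
    acc <- acc + inter / (tot - inter + eps)
  }
  1 - acc / length(present)
}

oracle_gjl <- function(p, t, eps = 1e-5) {
  N <- nrow(p); NC <- ncol(p)
  num <- 0; den <- 0
  for (c in seq_len(NC)) {
    v <- sum(t[, c])
    if (v == 0) next
    w <- 1 / v
    inter <- 0; tot <- 0
    for (i in seq_len(N)) {
      inter <- inter + p[i, c] * t[i, c]
      tot <- tot + p[i, c] + t[i, c]
    }
    num <- num + w * inter
    den <- den + w * (tot - inter)
  }
  if (den == 0) return(0)
  1 - num / (den + eps)
}

oracle_cce <- function(p, t, clip = 1e-7) {
  N <- nrow(p); NC <- ncol(p)
  acc <- 0
  for (i in seq_len(N)) {
    for (c in seq_len(NC)) {
      pc <- min(max(p[i, c], clip), 1 - clip)
      acc <- acc - t[i, c] * log(pc)
    }
  }
  acc / N
}

# Brute-force per-label Dice by explicit voxel counting.
oracle_dice <- function(a, b, label) {
  na <- 0; nb <- 0; nab <- 0
  for (i in seq_along(a)) {
    ia <- a[i] == label; ib <- b[i] == label
    na <- na + ia; nb <- nb + ib; nab <- nab + (ia && ib)
  }
  if (na + nb == 0) 1 else 2 * nab / (na + nb)
}

# Random probability/one-hot instance; optionally forces a class absent.
random_instance <- function(n = NULL, nc = NULL, absent = FALSE) {
  n <- n %||% sample(2:100, 1)
  nc <- nc %||% sample(2:5, 1)
  p <- matrix(runif(n * nc), n, nc)
  p <- p / rowSums(p)
  cls <- if (absent && nc > 2) sample(nc - 1, n, replace = TRUE)
         else sample(nc, n, replace = TRUE)
  t <- diag(nc)[cls, , drop = FALSE]
  list(p = p, t = t, n = n, nc = nc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
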
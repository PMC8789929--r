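#' Z-score intensity normalization
#'
#' Subtracts the mean and divides by the standard deviation, per channel
#' for multi-channel arrays.  Statistics are computed over the supplied
#' (already cropped) region, so normalization reflects the crop rather than
#' the whole head.
#'
#' @param x a 3D array, a 4D `(X,Y,Z,C)` array, or a `hippunet_sample`.
#' @return same type as `x`, each channel with mean 0 and sd 1.
#' @export
zscore_normalize <- function(x) {
  if (inherits(x, "hippunet_sample")) {
    x$image <- zscore_normalize(x$image)
    return(x)
  }
  d <- dim(x)
  norm1 <- function(v) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))     # population standard deviation
    if (!is.finite(s) || s == 0)
      stop("degenerate input: zero intensity variance")
    (v - m) / s
  }
  if (length(d) == 4L) {
    for (ch in seq_len(d[4])) x[, , , ch] <- norm1(x[, , , ch])
    x
  } else {
    array(norm1(x), d)
  }
}

#' Template-space crop box
#'
#' A half-open, 0-based voxel box `[start, end)` per axis, optionally
#' tagged with the anatomical side it covers.
#'
#' @param xlim,ylim,zlim integer 2-vectors `c(start, end)`, 0-based,
#'   half-open.
#' @param side optional `"left"`/`"right"` tag.
#' @return an object of class `crop_box`.
#' @export
crop_box <- function(xlim, ylim, zlim, side = NULL) {
  lims <- list(x = xlim, y = ylim, z = zlim)
  for (l in lims) stopifnot(length(l) == 2, l[2] > l[1], l[1] >= 0)
  structure(list(xlim = as.integer(xlim), ylim = as.integer(ylim),
                 zlim = as.integer(zlim), side = side),
            class = "crop_box")
}

#' Crop a volume to a box
#'
#' Extracts the sub-volume of a 3D/4D array (or `hippunet_sample`) covered
#' by a [crop_box()].  Spacing is preserved and the box origin is recorded
#' in the result (`attr(, "crop_origin")`, 0-based voxel offset) so the
#' crop is invertible with [uncrop_volume()].
#'
#' @param x array or `hippunet_sample`.
#' @param box a [crop_box()].
#' @return cropped object of the same type.
#' @export
crop_volume <- function(x, box) {
  stopifnot(inherits(box, "crop_box"))
  if (inherits(x, "hippunet_sample")) {
    x$image <- crop_volume(x$image, box)
    x$labels <- crop_volume(x$labels, box)
    if (!is.null(box$side)) x$side <- box$side
    return(x)
  }
  d <- dim(x)
  if (box$xlim[2] > d[1] || box$ylim[2] > d[2] || box$zlim[2] > d[3])
    stop("crop box exceeds volume bounds")
  ix <- (box$xlim[1] + 1):box$xlim[2]
  iy <- (box$ylim[1] + 1):box$ylim[2]
  iz <- (box$zlim[1] + 1):box$zlim[2]
  out <- if (length(d) == 4L) x[ix, iy, iz, , drop = FALSE]
         else x[ix, iy, iz, drop = FALSE]
  attr(out, "crop_origin") <- c(box$xlim[1], box$ylim[1], box$zlim[1])
  out
}

#' Paste a cropped volume back into a full-size volume
#'
#' @param cropped result of [crop_volume()] (carrying its origin).
#' @param full the target full-size array (modified copy returned).
#' @return `full` with the cropped voxels written back in place.
#' @export
uncrop_volume <- function(cropped, full) {
  org <- attr(cropped, "crop_origin")
  if (is.null(org)) stop("cropped volume carries no crop origin")
  d <- dim(cropped)
  ix <- org[1] + seq_len(d[1]); iy <- org[2] + seq_len(d[2])
  iz <- org[3] + seq_len(d[3])
  if (length(dim(full)) == 4L) full[ix, iy, iz, ] <- cropped
  else full[ix, iy, iz] <- cropped
  full
}

# --- cubic B-spline resampling ------------------------------------------

# In-place cubic B-spline prefilter along a vector (Unser's recursive
# filter, mirror boundaries), turning samples into spline coefficients.
bspline_prefilter_vec <- function(s) {
  z1 <- sqrt(3) - 2
  n <- length(s)
  if (n == 1) return(s)
  lambda <- 6
  s <- s * lambda
  cp <- numeric(n)
  # causal init: truncated sum of the infinite mirror expansion
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z1))))
  cp[1] <- sum(s[seq_len(horizon)] * z1^(seq_len(horizon) - 1))
  for (i in 2:n) cp[i] <- s[i] + z1 * cp[i - 1]
  cm <- numeric(n)
  cm[n] <- (z1 / (z1^2 - 1)) * (cp[n] + z1 * cp[n - 1])
  for (i in seq(n - 1, 1)) cm[i] <- z1 * (cm[i + 1] - cp[i])
  cm
}

bspline_kernel <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 2 / 3 - at^2 + at^3 / 2,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

# Interpolate a vector of spline samples at arbitrary positions (0-based).
# The signal is extended by antireflection (point mirror, slope-preserving)
# before prefiltering, so evaluation slightly beyond the last node
# extrapolates linearly instead of flattening out.
bspline_interp_vec <- function(s, pos) {
  n <- length(s)
  P <- min(8L, n - 1L)
  ext <- c(2 * s[1] - s[(P + 1):2], s, 2 * s[n] - s[(n - 1):(n - P)])
  c_ <- bspline_prefilter_vec(ext)
  ne <- length(ext)
  out <- numeric(length(pos))
  for (j in seq_along(pos)) {
    pj <- pos[j] + P
    i0 <- floor(pj) - 1
    acc <- 0
    for (i in i0:(i0 + 3)) {
      im <- min(max(i, 0), ne - 1)
      acc <- acc + c_[im + 1] * bspline_kernel(pj - i)
    }
    out[j] <- acc
  }
  out
}

# Separable B-spline interpolation of a 3D array onto per-axis positions.
bspline_resample3d <- function(x, pos_list) {
  for (axis in 1:3) {
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(x, perm)
    m <- matrix(ap, nrow = d[axis])
    out <- apply(m, 2L, function(col) bspline_interp_vec(col, pos_list[[axis]]))
    out <- matrix(out, nrow = length(pos_list[[axis]]))
    dim(out) <- c(length(pos_list[[axis]]), d[perm][-1])
    x <- aperm(out, order(perm))
  }
  x
}

#' Simulate standard-resolution acquisition and B-spline upsampling
#'
#' Reduces the resolution of a high-resolution channel by an integer
#' factor (grid decimation, optionally preceded by block averaging as an
#' anti-alias filter) and interpolates back onto the original grid with
#' cubic B-splines.  The output lives on the input grid and emulates
#' standard-resolution data upsampled to the high-resolution template.
#'
#' @param x 3D array (single channel) or 4D array (per channel).
#' @param factor integer downsampling factor (>= 2).
#' @param method interpolation method (`"bspline"`).
#' @param antialias apply block-mean averaging before decimation.
#' @return array on the original grid.
#' @export
downsample_upsample <- function(x, factor = 2L, method = "bspline",
                                antialias = FALSE) {
  method <- match.arg(method, "bspline")
  factor <- as.integer(factor)
  stopifnot(factor >= 2)
  d <- dim(x)
  if (length(d) == 4L) {
    for (ch in seq_len(d[4]))
      x[, , , ch] <- downsample_upsample(x[, , , ch], factor, method, antialias)
    return(x)
  }
  stopifnot(all(d %% factor == 0))
  lo <- x
  if (antialias) {
    lo <- gaussian_blur(lo, factor / 2.355)  # FWHM = new voxel size
  }
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  lo <- lo[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # coarse sample j (0-based) sits at fine coordinate j*factor; interpolate
  # the fine grid positions in coarse coordinates
  pos <- lapply(d, function(n) (seq_len(n) - 1) / factor)
  bspline_resample3d(lo, pos)
}

# --- NIfTI input/output --------------------------------------------------

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around the RNifti reader/writer.  `read_volume()` returns
#' the voxel array with the image attributes preserved; `write_volume()`
#' writes an array, optionally reusing a template's geometry and applying
#' a crop origin as a translation of the stored affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: the image array (class `niftiImage`).
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @param x array to write.
#' @param template optional `niftiImage` (or path) providing geometry.
#' @param spacing voxel spacing in mm, used when no template is given.
#' @export
write_volume <- function(x, path, template = NULL, spacing = c(0.5, 0.5, 0.5)) {
  org <- attr(x, "crop_origin")
  if (!is.null(template)) {
    img <- RNifti::asNifti(unclass(x), reference = template)
  } else {
    img <- RNifti::asNifti(unclass(x))
    RNifti::pixdim(img) <- rep(spacing, length.out = 3)
  }
  if (!is.null(org)) {
    xf <- RNifti::xform(img)
    xf[1:3, 4] <- xf[1:3, 4] + as.vector(xf[1:3, 1:3] %*% org)
    RNifti::qform(img) <- structure(xf, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- external preprocessing hooks ---------------------------------------

#' Configure external preprocessing commands
#'
#' The denoising, bias-field-correction and affine template registration
#' stages are performed by external tools; this package only orchestrates
#' them.  Each enabled step is a command template in which `{input}` and
#' `{output}` are substituted.  The canonical order is denoise, then bias
#' correction, then affine registration; supplying steps in another order
#' triggers a warning and reordering.
#'
#' @param denoise,bias,affine command templates (`NULL` disables a step).
#' @return an object of class `external_steps_config`.
#' @export
external_steps_config <- function(denoise = NULL, bias = NULL, affine = NULL) {
  structure(list(denoise = denoise, bias = bias, affine = affine),
            class = "external_steps_config")
}

#' Run the external preprocessing steps
#'
#' Applies the configured external commands in canonical order to each
#' input file, threading intermediate files through a scratch directory,
#' and records provenance.  With every step disabled this is the identity
#' on `paths`.
#'
#' @param paths character vector of input volume paths.
#' @param config an [external_steps_config()] (a plain named list is
#'   accepted; out-of-canonical-order names produce a warning).
#' @param work_dir directory for intermediate files.
#' @return list with `paths` (final file per input) and `provenance`
#'   (tibble: step, command, input, output).
#' @export
run_external_steps <- function(paths, config, work_dir = tempfile("prep")) {
  canonical <- c("denoise", "bias", "affine")
  nm <- names(config)[!vapply(config, is.null, logical(1))]
  if (!identical(nm, intersect(canonical, nm)))
    warning("external steps supplied out of canonical order ",
            "(denoise -> bias -> affine); running in canonical order")
  steps <- intersect(canonical, nm)
  if (length(steps) == 0)
    return(list(paths = paths, provenance = tibble::tibble(
      step = character(), command = character(),
      input = character(), output = character())))
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  out_paths <- character(length(paths))
  for (i in seq_along(paths)) {
    cur <- paths[i]
    for (s in steps) {
      out <- file.path(work_dir, paste0(s, "_", basename(cur)))
      cmd <- gsub("{output}", out, gsub("{input}", cur, config[[s]],
                                        fixed = TRUE), fixed = TRUE)
      status <- system(cmd)
      if (status != 0)
        stop("external step '", s, "' failed (command: ", cmd, ")")
      prov[[length(prov) + 1L]] <- tibble::tibble(
        step = s, command = cmd, input = cur, output = out)
      cur <- out
    }
    out_paths[i] <- cur
  }
  list(paths = out_paths, provenance = dplyr::bind_rows(prov))
}
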
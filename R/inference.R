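#' Segment a volume with stored or sample-specific normalization statistics
#'
#' Runs the network on one input volume and returns the full-resolution
#' segmentation.  `mode = "standard"` is ordinary evaluation-mode
#' prediction: normalization layers use the running statistics stored
#' during training.  `mode = "ttbn"` (training-time batch normalization)
#' instead normalizes every layer with the statistics of the presented
#' sample, computed per call — the batch-of-one training behaviour — while
#' keeping stochastic layers (dropout) disabled and leaving the stored
#' statistics untouched.  Sample statistics track the test volume's own
#' intensity distribution, which makes TTBN robust to global intensity
#' shifts between training and test data.
#'
#' Neither mode mutates the network: the model state is identical before
#' and after any prediction call.
#'
#' @param net a trained or initialized [build_ds_unet3d()] network.
#' @param x input volume array `(X, Y, Z, in_channels)`.
#' @param mode `"standard"` or `"ttbn"`.
#' @param argmax if `TRUE`, return the per-voxel most probable class as an
#'   integer label map (values `0..n_classes-1`) instead of probabilities.
#' @return the finest head's probability array `(X, Y, Z, n_classes)`, or
#'   an integer 3D label map when `argmax = TRUE`.
#' @export
predict_volume <- function(net, x, mode = c("standard", "ttbn"), argmax = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ds_unet3d"))
  if (mode == "ttbn") {
    audit <- parameter_audit(net$spec)
    if (!any(audit$kind == "batchnorm"))
      stop("ttbn prediction requires a network with normalization layers")
  }
  fwd <- net_forward(net, x, mode = mode)
  p <- fwd$probs$high
  if (!argmax) return(p)
  d <- dim(p)
  m <- matrix(p, ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[1:3])
}
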
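#' Tidy a trained model's history
#'
#' @param x a `hippunet_fit`.
#' @param ... unused.
#' @return the per-epoch loss history as a tibble (`epoch`, `split`,
#'   `loss`).
#' @export
tidy.hippunet_fit <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x a `hippunet_fit`.
#' @param ... unused.
#' @return tibble with the optimizer steps, final training loss, best
#'   validation loss and parameter count.
#' @export
glance.hippunet_fit <- function(x, ...) {
  h <- x$history
  tr <- h[h$split == "train", ]
  va <- h[h$split == "validation", ]
  tibble::tibble(
    steps = x$steps,
    epochs = max(h$epoch),
    final_train_loss = tr$loss[nrow(tr)],
    best_validation_loss = if (nrow(va)) min(va$loss) else NA_real_,
    n_parameters = count_parameters(x$network))
}

#' Tidy cross-validation results
#'
#' @param x a `hippunet_cv`.
#' @param ... unused.
#' @return the per-sample per-structure Dice tibble.
#' @export
tidy.hippunet_cv <- function(x, ...) x$reports

#' @rdname tidy.hippunet_cv
#' @export
glance.hippunet_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "structure",
                       values_from = c("mean", "sd"), id_cols = "mode")
}

#' Plot a training history
#'
#' @param object a `hippunet_fit`.
#' @param ... unused.
#' @return a ggplot of loss against epoch per split.
#' @export
autoplot.hippunet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "multiscale loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Dice report
#'
#' @param object a `dice_report`.
#' @param ... unused.
#' @return a ggplot bar chart of Dice per structure.
#' @export
autoplot.dice_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$structure, y = .data$dice)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice") +
    ggplot2::theme_minimal()
}

#' Plot the central slices of a sample
#'
#' @param object a `hippunet_sample`.
#' @param channel image channel to show.
#' @param ... unused.
#' @return a ggplot raster of the central axial slice with label contours.
#' @export
autoplot.hippunet_sample <- function(object, channel = 1L, ...) {
  j <- ceiling(dim(object$labels)[2] / 2)
  img <- object$image[, j, , channel]
  lab <- object$labels[, j, ]
  df <- expand.grid(x = seq_len(nrow(img)), z = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  df$label <- factor(as.vector(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = df[df$label != "0", ],
                        ggplot2::aes(colour = .data$label), size = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
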
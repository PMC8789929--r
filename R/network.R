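#' Declarative specification of the deeply supervised 3D U-Net
#'
#' Describes the multi-resolution encoder-decoder used for hippocampus
#' subfield segmentation: `levels` resolution levels whose filter counts
#' double on the way down (`base_filters`, `2*base_filters`, ...) and halve
#' on the way up, `blocks_per_level` convolution blocks per level (each
#' block is batch normalization, a 3x3x3 "same" convolution, then ReLU; the
#' very first block operates on the raw input channels without
#' normalization), dropout in the encoding path only, 2x max-pooling between
#' levels, and parameter-free nearest-neighbour upsampling in the decoder
#' with encoder shortcut concatenation.
#'
#' With `deep_supervision = TRUE` the decoder carries a 1x1x1
#' softmax head at each of its (up to) three finest levels, and the
#' upsampled coarse segmentation outputs feed the next finer output:
#' `feedback = "additive"` (default) adds the upsampled coarser head logits
#' to the finer head logits — a parameter-free coarse-to-fine refinement
#' (adding logits multiplies the coarse probabilities in, acting as a
#' spatial prior); `feedback = "concat"` instead concatenates the upsampled
#' coarser class probabilities as extra input channels of the next decoder
#' level; `feedback = "none"` disables the coupling (plain multi-head deep
#' supervision).  With `deep_supervision = FALSE` the graph is the classic
#' single-output 3D U-Net comparator.
#'
#' @param in_channels input channels (2 for paired T1w/T2w volumes).
#' @param n_classes output classes including background.
#' @param levels number of resolution levels (4 spans 0.5 mm to 4 mm at the
#'   native 0.5 mm crop resolution).
#' @param base_filters filters at the finest level.
#' @param blocks_per_level convolution blocks per resolution level.
#' @param dropout_rate dropout rate in the encoding path.
#' @param deep_supervision attach multi-scale supervision heads?
#' @param feedback coarse-to-fine output feedback wiring.
#' @param spacing_mm voxel size of the finest level, used only for labelling.
#' @return an object of class `hippunet_spec`.
#' @examples
#' spec <- network_spec(levels = 2, base_filters = 4, n_classes = 3)
#' count_parameters(spec)
#' @export
network_spec <- function(in_channels = 2, n_classes = 4, levels = 4,
                         base_filters = 64, blocks_per_level = 3,
                         dropout_rate = 0.5, deep_supervision = TRUE,
                         feedback = c("additive", "concat", "none"),
                         spacing_mm = 0.5) {
  feedback <- match.arg(feedback)
  stopifnot(levels >= 1, base_filters >= 1, blocks_per_level >= 1,
            n_classes >= 2, in_channels >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    levels = as.integer(levels),
    base_filters = as.integer(base_filters),
    blocks_per_level = as.integer(blocks_per_level),
    dropout_rate = dropout_rate,
    deep_supervision = isTRUE(deep_supervision),
    feedback = feedback,
    spacing_mm = spacing_mm
  ), class = "hippunet_spec")
}

#' @export
print.hippunet_spec <- function(x, ...) {
  cat("DS-UNET3D spec:", x$levels, "levels, base", x$base_filters,
      "filters,", x$blocks_per_level, "blocks/level,",
      x$n_classes, "classes,",
      if (x$deep_supervision) paste0("deep supervision (feedback: ", x$feedback, ")")
      else "single head", "\n")
  invisible(x)
}

spec_filters <- function(spec) as.integer(spec$base_filters * 2^(seq_len(spec$levels) - 1L))

# Decoder levels carrying a supervision head, coarse to fine.
head_levels <- function(spec) {
  if (spec$levels == 1L) return(1L)
  dec <- seq_len(spec$levels - 1L)                  # decoder levels, fine..coarse = 1..levels-1
  if (!spec$deep_supervision) return(1L)
  sort(utils::head(dec, 3L), decreasing = TRUE)     # up to three finest, coarse first
}

# Decoder levels whose input concatenation carries upsampled coarse-output
# probability channels (concat feedback only).
concat_feedback_levels <- function(spec) {
  if (!spec$deep_supervision || spec$feedback != "concat") return(integer())
  hl <- head_levels(spec)
  if (length(hl) < 2L) return(integer())
  hl[-1L]                                           # receivers: one below each coarser head
}

#' Per-layer parameter audit
#'
#' Enumerates every parameterised layer of the network a spec describes,
#' with its kind, shape and parameter counts, as a tibble suitable for
#' auditing total parameter figures.  Normalization layers carry two
#' trainable per-channel parameters (scale, shift) and two per-channel
#' running statistics (mean, variance); the latter are listed in `n_stats`.
#'
#' @param spec a [network_spec()] (a built network is also accepted).
#' @return a tibble with one row per parameterised layer.
#' @seealso [count_parameters()]
#' @export
parameter_audit <- function(spec) {
  if (inherits(spec, "ds_unet3d")) spec <- spec$spec
  stopifnot(inherits(spec, "hippunet_spec"))
  F <- spec_filters(spec)
  rows <- list()
  add <- function(stage, name, kind, cin, cout, kernel, nk, nb, naff, nst) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = stage, layer = name, kind = kind,
      in_ch = as.integer(cin), out_ch = as.integer(cout),
      kernel = as.integer(kernel), n_kernel = as.integer(nk),
      n_bias = as.integer(nb), n_affine = as.integer(naff),
      n_stats = as.integer(nst))
  }
  cin <- spec$in_channels
  for (L in seq_len(spec$levels)) {
    for (b in seq_len(spec$blocks_per_level)) {
      if (!(L == 1L && b == 1L))
        add("encoder", sprintf("enc%db%d.bn", L, b), "batchnorm", cin, cin, NA,
            0L, 0L, 2L * cin, 2L * cin)
      add("encoder", sprintf("enc%db%d.conv", L, b), "conv3x3x3", cin, F[L], 3L,
          27L * cin * F[L], F[L], 0L, 0L)
      cin <- F[L]
    }
  }
  if (spec$levels > 1L) {
    fbl <- concat_feedback_levels(spec)
    below <- F[spec$levels]
    for (L in seq(spec$levels - 1L, 1L)) {
      cin <- below + F[L] + if (L %in% fbl) spec$n_classes else 0L
      for (b in seq_len(spec$blocks_per_level)) {
        add("decoder", sprintf("dec%db%d.bn", L, b), "batchnorm", cin, cin, NA,
            0L, 0L, 2L * cin, 2L * cin)
        add("decoder", sprintf("dec%db%d.conv", L, b), "conv3x3x3", cin, F[L], 3L,
            27L * cin * F[L], F[L], 0L, 0L)
        cin <- F[L]
      }
      below <- F[L]
    }
  }
  for (L in head_levels(spec)) {
    add("head", sprintf("head%d", L), "conv1x1x1", F[L], spec$n_classes, 1L,
        F[L] * spec$n_classes, spec$n_classes, 0L, 0L)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
    n_trainable = .data$n_kernel + .data$n_bias + .data$n_affine,
    n_total = .data$n_trainable + .data$n_stats)
}

#' Count network parameters
#'
#' Total parameter count of the network described by a spec (or of a built
#' network), summed over convolution kernels, biases and normalization
#' parameters.  By default the count includes the per-channel normalization
#' statistics (running mean and variance), matching the parameter totals
#' that deep-learning toolkits print in their model summaries; set
#' `include_stats = FALSE` for the strictly trainable subset (kernels,
#' biases, normalization scale and shift only).  The count is a pure
#' function of the spec and does not depend on the input volume size.
#'
#' @param spec a [network_spec()] or built network.
#' @param include_stats include normalization running statistics in the
#'   total (model-summary convention).
#' @return integer parameter count.
#' @export
count_parameters <- function(spec, include_stats = TRUE) {
  audit <- parameter_audit(spec)
  if (include_stats) sum(audit$n_total) else sum(audit$n_trainable)
}

#' Write the parameter audit as TSV
#'
#' @param spec a [network_spec()] or built network.
#' @param path output file path.
#' @return the audit tibble, invisibly.
#' @export
write_parameter_audit <- function(spec, path) {
  audit <- parameter_audit(spec)
  utils::write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(audit)
}

#' Read or write a network spec as YAML
#'
#' @param spec a [network_spec()].
#' @param path YAML file path.
#' @return `write_network_spec()` returns `path` invisibly;
#'   `read_network_spec()` returns a [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hippunet_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  do.call(network_spec, yaml::read_yaml(path))
}

#' Build the deeply supervised 3D U-Net
#'
#' Instantiates the network a [network_spec()] describes, with seeded
#' He-style weight initialization.  The returned object holds the trainable
#' parameters, the normalization running statistics, and the spec; it is a
#' plain value (training and prediction never mutate it in place).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `ds_unet3d`.
#' @export
build_ds_unet3d <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "hippunet_spec"))
  F <- spec_filters(spec)
  params <- list()
  buffers <- list()
  with_seed(derive_seed(seed, 1L), {
    audit <- parameter_audit(spec)
    for (i in seq_len(nrow(audit))) {
      nm <- audit$layer[i]
      if (audit$kind[i] == "batchnorm") {
        c_ <- audit$in_ch[i]
        params[[paste0(nm, ".gamma")]] <- rep(1, c_)
        params[[paste0(nm, ".beta")]] <- rep(0, c_)
        buffers[[paste0(nm, ".mean")]] <- rep(0, c_)
        buffers[[paste0(nm, ".var")]] <- rep(1, c_)
      } else if (audit$kind[i] == "conv3x3x3") {
        cin <- audit$in_ch[i]; cout <- audit$out_ch[i]
        sd_w <- sqrt(2 / (27 * cin))
        params[[paste0(nm, ".w")]] <-
          array(rnorm(27 * cin * cout, sd = sd_w), c(3, 3, 3, cin, cout))
        params[[paste0(nm, ".b")]] <- rep(0, cout)
      } else {                                     # conv1x1x1 head
        cin <- audit$in_ch[i]; cout <- audit$out_ch[i]
        params[[paste0(nm, ".w")]] <-
          matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
        params[[paste0(nm, ".b")]] <- rep(0, cout)
      }
    }
  })
  structure(list(spec = spec, params = params, buffers = buffers),
            class = "ds_unet3d")
}

#' @export
print.ds_unet3d <- function(x, ...) {
  print(x$spec)
  cat("parameters:", format(count_parameters(x), big.mark = ","),
      "(", format(count_parameters(x, include_stats = FALSE), big.mark = ","),
      "trainable )\n")
  invisible(x)
}

check_input_dims <- function(spec, x) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != spec$in_channels)
    stop("input must be an (X, Y, Z, ", spec$in_channels, ") array")
  div <- 2^(spec$levels - 1L)
  bad <- which(d[1:3] %% div != 0)
  if (length(bad))
    stop("spatial dimension ", paste(c("X", "Y", "Z")[bad], collapse = ", "),
         " not divisible by ", div, " (levels = ", spec$levels, ")")
}

# Run one conv block stack (BN -> conv -> ReLU per block).
# Returns output plus per-block caches and, in training mode, running-stat
# updates.  `prefix` identifies parameters; `skip_first_bn` drops the
# normalization of the very first encoder block.
run_blocks <- function(net, x, prefix, mode, skip_first_bn = FALSE,
                       collect = TRUE) {
  spec <- net$spec
  caches <- vector("list", spec$blocks_per_level)
  updates <- list()
  for (b in seq_len(spec$blocks_per_level)) {
    nm <- sprintf("%sb%d", prefix, b)
    bn_in <- NULL
    has_bn <- !(skip_first_bn && b == 1L)
    if (has_bn) {
      gamma <- net$params[[paste0(nm, ".bn.gamma")]]
      beta <- net$params[[paste0(nm, ".bn.beta")]]
      if (mode == "standard") {
        stats <- list(mean = net$buffers[[paste0(nm, ".bn.mean")]],
                      var = net$buffers[[paste0(nm, ".bn.var")]])
      } else {
        stats <- channel_stats(x)
        if (mode == "train") {
          m <- BN_MOMENTUM
          updates[[paste0(nm, ".bn.mean")]] <-
            m * net$buffers[[paste0(nm, ".bn.mean")]] + (1 - m) * stats$mean
          updates[[paste0(nm, ".bn.var")]] <-
            m * net$buffers[[paste0(nm, ".bn.var")]] + (1 - m) * stats$var
        }
      }
      bn <- bn_forward(x, gamma, beta, stats)
      conv_in <- bn$y
    } else {
      bn <- NULL
      conv_in <- x
    }
    y <- conv3_forward(conv_in, net$params[[paste0(nm, ".conv.w")]],
                       net$params[[paste0(nm, ".conv.b")]])
    y <- relu_forward(y)
    if (collect)
      caches[[b]] <- list(bn = if (has_bn) list(xhat = bn$xhat, invstd = bn$invstd),
                          conv_in = conv_in, relu_out = y, has_bn = has_bn)
    x <- y
  }
  list(y = x, caches = caches, updates = updates)
}

# Backward through a block stack; returns gradient wrt the stack input and
# accumulates parameter gradients into `grads` (an environment).
blocks_backward <- function(net, g, prefix, caches, grads, batch_stats) {
  spec <- net$spec
  for (b in rev(seq_len(spec$blocks_per_level))) {
    nm <- sprintf("%sb%d", prefix, b)
    cb <- caches[[b]]
    g <- relu_backward(g, cb$relu_out)
    cv <- conv3_backward(cb$conv_in, net$params[[paste0(nm, ".conv.w")]], g)
    acc_grad(grads, paste0(nm, ".conv.w"), cv$gw)
    acc_grad(grads, paste0(nm, ".conv.b"), cv$gb)
    g <- cv$gx
    if (cb$has_bn) {
      bb <- bn_backward(g, net$params[[paste0(nm, ".bn.gamma")]], cb$bn,
                        batch = batch_stats)
      acc_grad(grads, paste0(nm, ".bn.gamma"), bb$dgamma)
      acc_grad(grads, paste0(nm, ".bn.beta"), bb$dbeta)
      g <- bb$gx
    }
  }
  g
}

acc_grad <- function(env, name, value) {
  if (is.null(env[[name]])) env[[name]] <- value
  else env[[name]] <- env[[name]] + value
}

#' Forward pass through the network
#'
#' Runs the network on a single input volume and returns the per-voxel
#' class probability field of every supervision head.  Modes:
#' `"standard"` normalizes with the stored running statistics (ordinary
#' evaluation-mode prediction), `"ttbn"` normalizes with the statistics of
#' the presented sample without touching the stored ones, and `"train"`
#' additionally updates the running statistics and applies dropout.
#'
#' @param net a built [build_ds_unet3d()] network.
#' @param x input array `(X, Y, Z, in_channels)`; spatial dims must be
#'   divisible by `2^(levels-1)`.
#' @param mode `"standard"`, `"ttbn"` or `"train"`.
#' @param collect_cache keep intermediate activations (needed for
#'   [net_backward()]).
#' @return list with `probs` (named list of probability arrays, finest
#'   first: `high`, then `medium`, `low` when deep supervision is on),
#'   `logits`, `buffer_updates` (training mode), and `cache` when requested.
#' @export
net_forward <- function(net, x, mode = c("standard", "ttbn", "train"),
                        collect_cache = FALSE) {
  mode <- match.arg(mode)
  spec <- net$spec
  check_input_dims(spec, x)
  hl <- head_levels(spec)
  fbl <- concat_feedback_levels(spec)
  cache <- list(enc = list(), dec = list())
  updates <- list()

  # encoder
  skips <- list()
  h <- x
  for (L in seq_len(spec$levels)) {
    bl <- run_blocks(net, h, sprintf("enc%d", L), mode,
                     skip_first_bn = (L == 1L), collect = collect_cache)
    updates <- c(updates, bl$updates)
    h <- bl$y
    drop_mask <- NULL
    if (mode == "train" && spec$dropout_rate > 0) {
      dr <- dropout_forward(h, spec$dropout_rate)
      h <- dr$y
      drop_mask <- dr$mask
    }
    skips[[L]] <- h
    pool <- NULL
    if (L < spec$levels) {
      pool <- maxpool_forward(h)
      cache$enc[[L]] <- list(blocks = bl$caches, drop_mask = drop_mask,
                             pool_idx = pool$idx, out_dims = dim(h))
      h <- pool$y
    } else {
      cache$enc[[L]] <- list(blocks = bl$caches, drop_mask = drop_mask,
                             out_dims = dim(h))
    }
  }

  # decoder
  feats <- list()
  logits_raw <- list()
  probs_fb <- list()
  logits_eff <- list()
  if (spec$levels == 1L) {
    feats[[1L]] <- h
  } else {
    below <- h
    for (L in seq(spec$levels - 1L, 1L)) {
      up <- upsample_forward(below)
      parts <- list(up, skips[[L]])
      if (L %in% fbl)
        parts <- c(parts, list(upsample_forward(probs_fb[[L + 1L]])))
      cat_in <- do.call(concat_channels, parts)
      bl <- run_blocks(net, cat_in, sprintf("dec%d", L), mode, collect = collect_cache)
      updates <- c(updates, bl$updates)
      feats[[L]] <- bl$y
      cache$dec[[L]] <- list(blocks = bl$caches,
                             sizes = vapply(parts, function(p) dim(p)[4], integer(1)),
                             up_dims = dim(below))
      if (L %in% hl) {
        z <- conv1_forward(feats[[L]], net$params[[sprintf("head%d.w", L)]],
                           net$params[[sprintf("head%d.b", L)]])
        logits_raw[[L]] <- z
        zeff <- z
        if (spec$feedback == "additive" && (L + 1L) %in% hl)
          zeff <- z + upsample_forward(logits_eff[[L + 1L]])
        logits_eff[[L]] <- zeff
        probs_fb[[L]] <- softmax(zeff)
      }
      below <- feats[[L]]
    }
  }
  if (spec$levels == 1L) {
    z <- conv1_forward(feats[[1L]], net$params[["head1.w"]], net$params[["head1.b"]])
    logits_raw[[1L]] <- z
    logits_eff[[1L]] <- z
    probs_fb[[1L]] <- softmax(z)
  }

  scale_names <- c("high", "medium", "low")
  fine_first <- sort(hl)
  probs <- setNames(lapply(fine_first, function(L) probs_fb[[L]]),
                    scale_names[seq_along(fine_first)])
  logits <- setNames(lapply(fine_first, function(L) logits_eff[[L]]),
                     scale_names[seq_along(fine_first)])
  out <- list(probs = probs, logits = logits, head_levels = hl,
              buffer_updates = updates)
  if (collect_cache)
    out$cache <- c(cache, list(feats = feats, logits_eff = logits_eff,
                               probs_fb = probs_fb, x_dims = dim(x)))
  out
}

#' Backward pass through the network
#'
#' Backpropagates loss gradients taken with respect to the effective head
#' logits (finest head first, as returned by [net_forward()]) through the
#' whole graph, returning parameter gradients.
#'
#' @param net the network used for the forward pass.
#' @param fwd the result of `net_forward(..., collect_cache = TRUE)` in
#'   `"train"` mode.
#' @param grad_logits named list (`high`, `medium`, `low`) of gradients wrt
#'   the corresponding effective logits; missing heads get zero gradient.
#' @param batch_stats `TRUE` when the forward pass normalized with batch
#'   statistics (training/TTBN).
#' @return named list of parameter gradients matching `net$params`.
#' @export
net_backward <- function(net, fwd, grad_logits, batch_stats = TRUE) {
  spec <- net$spec
  cache <- fwd$cache
  stopifnot(!is.null(cache))
  hl <- fwd$head_levels
  fbl <- concat_feedback_levels(spec)
  grads <- new.env(parent = emptyenv())

  fine_first <- sort(hl)
  scale_names <- c("high", "medium", "low")
  g_eff <- list()
  for (i in seq_along(fine_first)) {
    g <- grad_logits[[scale_names[i]]]
    L <- fine_first[i]
    g_eff[[L]] <- if (is.null(g)) array(0, dim(cache$logits_eff[[L]])) else g
  }
  # additive feedback: effective logits chain fine -> coarse
  if (spec$feedback == "additive" && length(hl) > 1L) {
    for (L in sort(hl)) {
      if ((L + 1L) %in% hl)
        g_eff[[L + 1L]] <- g_eff[[L + 1L]] + upsample_backward(g_eff[[L]])
    }
  }
  g_raw <- g_eff  # gradient wrt raw head conv output equals eff-logit grad

  g_enc_out <- vector("list", spec$levels)
  if (spec$levels == 1L) {
    hb <- conv1_backward(cache$feats[[1L]], net$params[["head1.w"]], g_raw[[1L]])
    acc_grad(grads, "head1.w", hb$gw)
    acc_grad(grads, "head1.b", hb$gb)
    g_enc_out[[1L]] <- hb$gx
  } else {
    g_feat <- vector("list", spec$levels - 1L)
    g_bottleneck <- NULL
    for (L in seq_len(spec$levels - 1L)) {       # fine -> coarse
      g <- g_feat[[L]]
      if (is.null(g)) g <- array(0, dim(cache$feats[[L]]))
      if (L %in% hl) {
        hb <- conv1_backward(cache$feats[[L]], net$params[[sprintf("head%d.w", L)]],
                             g_raw[[L]])
        acc_grad(grads, sprintf("head%d.w", L), hb$gw)
        acc_grad(grads, sprintf("head%d.b", L), hb$gb)
        g <- g + hb$gx
      }
      g <- blocks_backward(net, g, sprintf("dec%d", L), cache$dec[[L]]$blocks,
                           grads, batch_stats)
      parts <- split_channels(g, cache$dec[[L]]$sizes)
      g_up <- upsample_backward(parts[[1L]])
      if (L + 1L <= spec$levels - 1L) {
        g_feat[[L + 1L]] <- if (is.null(g_feat[[L + 1L]])) g_up
                            else g_feat[[L + 1L]] + g_up
      } else {
        g_bottleneck <- g_up
      }
      g_enc_out[[L]] <- parts[[2L]]
      if (L %in% fbl) {
        g_prob <- upsample_backward(parts[[3L]])
        gz <- softmax_backward(g_prob, cache$probs_fb[[L + 1L]])
        g_raw[[L + 1L]] <- g_raw[[L + 1L]] + gz
      }
    }
    g_enc_out[[spec$levels]] <- g_bottleneck
  }

  # encoder, top (coarsest) to bottom
  g_below_in <- NULL
  for (L in seq(spec$levels, 1L)) {
    g <- g_enc_out[[L]]
    if (is.null(g)) g <- array(0, cache$enc[[L]]$out_dims)
    if (L < spec$levels)
      g <- g + maxpool_backward(g_below_in, cache$enc[[L]]$pool_idx,
                                cache$enc[[L]]$out_dims)
    if (!is.null(cache$enc[[L]]$drop_mask))
      g <- dropout_backward(g, cache$enc[[L]]$drop_mask)
    g_below_in <- blocks_backward(net, g, sprintf("enc%d", L),
                                  cache$enc[[L]]$blocks, grads, batch_stats)
  }
  as.list(grads)
}

# Apply accumulated running-statistic updates from a training forward pass.
apply_buffer_updates <- function(net, updates) {
  for (nm in names(updates)) net$buffers[[nm]] <- updates[[nm]]
  net
}
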
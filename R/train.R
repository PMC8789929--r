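#' Training configuration
#'
#' Hyper-parameters of the training loop.  Defaults follow the reference
#' protocol: generalized Jaccard loss, Adam with default parameters,
#' batches of one volume, 200 epochs, and multiscale supervision weights
#' emphasising the full-resolution head.
#'
#' @param loss training objective: `"cce"`, `"dl"`, `"gdl"`, `"jl"` or
#'   `"gjl"`.
#' @param epochs maximum number of passes over the training set.
#' @param max_steps optional cap on total optimizer steps (overrides
#'   `epochs` when reached first).
#' @param learning_rate,beta1,beta2,adam_eps Adam parameters.
#' @param batch_size training batch size (volumes per step; 1 matches the
#'   reference protocol and the per-sample normalization statistics).
#' @param scale_weights multiscale loss weights, coarse to fine; `NULL`
#'   selects the defaults `(0.1, 0.2, 0.7)` adapted to the number of heads.
#' @param augment an [augment_config()], or `NULL` to disable
#'   augmentation.
#' @param jl_literal evaluate the pooled-ratio Jaccard variant instead of
#'   the per-class mean when `loss = "jl"`.
#' @param checkpoint `"best"` keeps the parameters with the lowest
#'   validation loss; `"last"` keeps the final parameters.
#' @param seed master seed for initialization, shuffling, dropout and
#'   augmentation.
#' @param run_dir optional directory where the config, history and final
#'   checkpoint are persisted.
#' @param verbose print per-epoch losses.
#' @return an object of class `training_config`.
#' @export
training_config <- function(loss = "gjl", epochs = 200L, max_steps = NULL,
                            learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-7, batch_size = 1L,
                            scale_weights = NULL,
                            augment = augment_config(),
                            jl_literal = FALSE,
                            checkpoint = c("best", "last"),
                            seed = 1L, run_dir = NULL, verbose = FALSE) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(loss = loss, epochs = as.integer(epochs),
                 max_steps = max_steps, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 batch_size = as.integer(batch_size),
                 scale_weights = scale_weights, augment = augment,
                 jl_literal = jl_literal, checkpoint = checkpoint,
                 seed = as.integer(seed), run_dir = run_dir,
                 verbose = isTRUE(verbose)),
            class = "training_config")
}

# Per-scale one-hot target pyramid for the supervision heads: the label map
# is majority-vote downsampled per coarse voxel so coarse targets stay
# valid hard label fields (no vocabulary invented or lost for structures
# thicker than the coarse voxel).
target_pyramid <- function(labels, n_classes, levels_needed) {
  out <- list()
  lab <- labels
  for (L in seq_len(max(levels_needed))) {
    if (L > 1L)
      lab <- .label_downsample2(lab, dim(lab), n_classes)
    if (L %in% levels_needed)
      out[[L]] <- one_hot_volume(lab, n_classes)
  }
  out
}

# Composite multiscale loss and effective-logit gradients for one sample.
multiscale_step <- function(fwd, targets, lossdef, weights, hl) {
  fine_first <- sort(hl)
  scale_names <- c("high", "medium", "low")
  losses <- numeric(length(fine_first))
  grads <- list()
  for (i in seq_along(fine_first)) {
    L <- fine_first[i]
    p <- fwd$probs[[scale_names[i]]]
    t <- targets[[L]]
    losses[i] <- lossdef$value(p, t)
    gp <- weights[[scale_names[i]]] * lossdef$gradient(p, t)
    grads[[scale_names[i]]] <- softmax_backward(gp, p)
  }
  w <- unlist(weights[scale_names[seq_along(fine_first)]])
  list(total = sum(w * losses), per_scale = setNames(losses, scale_names[seq_along(fine_first)]),
       grad_logits = grads)
}

scale_weight_list <- function(cfg, hl) {
  h <- length(hl)
  w <- cfg$scale_weights %||% default_scale_weights(h)
  if (length(w) != h) stop("need ", h, " scale weights, got ", length(w))
  # supplied coarse->fine; heads named fine-first
  setNames(as.list(rev(w)), c("high", "medium", "low")[seq_len(h)])
}

#' Train a network on labelled volumes
#'
#' Runs seeded stochastic training of a [build_ds_unet3d()] network with
#' the Adam optimizer, batch size one, optional augmentation
#' (smooth/sharpen and mixup), multiscale deep supervision, and per-epoch
#' validation.  Ground truth is majority-vote downsampled to every
#' supervision scale.  All randomness derives from `cfg$seed`, so a fixed
#' seed reproduces the loss history exactly.
#'
#' @param spec a [network_spec()] (or an already built `ds_unet3d` to
#'   continue training).
#' @param samples training samples: list of `hippunet_sample` objects.
#' @param cfg a [training_config()].
#' @param validation optional list of held-out samples for validation
#'   loss tracking and checkpoint selection.
#' @return an object of class `hippunet_fit`: the selected network
#'   (`network`), the last-step network (`final_network`), the per-epoch
#'   `history` tibble, the config, and the number of optimizer steps run.
#' @export
train_network <- function(spec, samples, cfg = training_config(),
                          validation = NULL) {
  net <- if (inherits(spec, "ds_unet3d")) spec
         else build_ds_unet3d(spec, seed = cfg$seed)
  spec <- net$spec
  hl <- head_levels(spec)
  weights <- scale_weight_list(cfg, hl)
  lossdef <- resolve_loss(cfg$loss)
  if (cfg$loss == "jl" && cfg$jl_literal) {
    lossdef$value <- function(p, t) jaccard_loss(p, t, literal = TRUE)
  }

  targets <- lapply(samples, function(s)
    target_pyramid(s$labels, spec$n_classes, hl))
  val_targets <- lapply(validation %||% list(), function(s)
    target_pyramid(s$labels, spec$n_classes, hl))

  adam_m <- list(); adam_v <- list(); adam_t <- 0L
  history <- list()
  best <- list(loss = Inf, net = net)
  step <- 0L
  done <- FALSE

  eval_loss <- function(net, xs, ts) {
    ls <- vapply(seq_along(xs), function(i) {
      fwd <- net_forward(net, xs[[i]]$image, mode = "standard")
      multiscale_step(fwd, ts[[i]], lossdef, weights, hl)$total
    }, numeric(1))
    mean(ls)
  }

  for (epoch in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, 1000L + epoch))
    order_ <- sample(seq_along(samples))
    epoch_losses <- numeric(0)
    for (i in order_) {
      s <- samples[[i]]
      t_pyr <- targets[[i]]
      img <- s$image
      if (!is.null(cfg$augment)) {
        if (runif(1) < cfg$augment$p_smooth_sharpen)
          img <- smooth_sharpen(img, cfg$augment,
                                seed = derive_seed(cfg$seed, step * 7L + 1L))
        if (length(samples) > 1L && runif(1) < cfg$augment$p_mixup) {
          j <- sample(setdiff(seq_along(samples), i), 1L)
          lam <- rbeta(1, cfg$augment$mixup_alpha, cfg$augment$mixup_alpha)
          img <- lam * img + (1 - lam) * samples[[j]]$image
          mix <- list()
          for (L in hl)
            mix[[L]] <- lam * targets[[i]][[L]] + (1 - lam) * targets[[j]][[L]]
          t_pyr <- mix
        }
      }
      fwd <- net_forward(net, img, mode = "train", collect_cache = TRUE)
      ms <- multiscale_step(fwd, t_pyr, lossdef, weights, hl)
      if (!is.finite(ms$total))
        stop("non-finite training loss at step ", step + 1L,
             " (sample ", s$subject %||% i, "); aborting")
      grads <- net_backward(net, fwd, ms$grad_logits, batch_stats = TRUE)
      net <- apply_buffer_updates(net, fwd$buffer_updates)
      adam_t <- adam_t + 1L
      c1 <- 1 - cfg$beta1^adam_t; c2 <- 1 - cfg$beta2^adam_t
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adam_m[[nm]] <- if (is.null(adam_m[[nm]])) (1 - cfg$beta1) * g
                        else cfg$beta1 * adam_m[[nm]] + (1 - cfg$beta1) * g
        adam_v[[nm]] <- if (is.null(adam_v[[nm]])) (1 - cfg$beta2) * g^2
                        else cfg$beta2 * adam_v[[nm]] + (1 - cfg$beta2) * g^2
        net$params[[nm]] <- net$params[[nm]] -
          cfg$learning_rate * (adam_m[[nm]] / c1) /
          (sqrt(adam_v[[nm]] / c2) + cfg$adam_eps)
      }
      epoch_losses <- c(epoch_losses, ms$total)
      step <- step + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
    }
    history[[length(history) + 1L]] <- tibble::tibble(
      epoch = epoch, split = "train", loss = mean(epoch_losses))
    if (length(val_targets)) {
      vl <- eval_loss(net, validation, val_targets)
      history[[length(history) + 1L]] <- tibble::tibble(
        epoch = epoch, split = "validation", loss = vl)
      if (vl < best$loss) best <- list(loss = vl, net = net)
    }
    if (cfg$verbose)
      message(sprintf("epoch %d: train %.4f%s", epoch, mean(epoch_losses),
                      if (length(val_targets))
                        sprintf(", val %.4f", utils::tail(history, 1)[[1]]$loss)
                      else ""))
    if (done) break
  }

  selected <- if (cfg$checkpoint == "best" && is.finite(best$loss)) best$net else net
  fit <- structure(list(network = selected, final_network = net,
                        history = dplyr::bind_rows(history),
                        config = cfg, steps = step),
                   class = "hippunet_fit")
  if (!is.null(cfg$run_dir)) persist_run(fit, cfg$run_dir)
  fit
}

persist_run <- function(fit, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$history, file.path(run_dir, "history.csv"),
                   row.names = FALSE)
  cfg <- fit$config
  cfg$augment <- if (!is.null(cfg$augment)) unclass(cfg$augment)
  yaml::write_yaml(unclass(cfg), file.path(run_dir, "config.yaml"))
  saveRDS(fit$network, file.path(run_dir, "checkpoint.rds"))
  invisible(run_dir)
}

#' @export
print.hippunet_fit <- function(x, ...) {
  cat("hippunet fit:", x$steps, "optimizer steps\n")
  print(utils::tail(x$history, 4))
  invisible(x)
}

#' K-fold cross-validated training and evaluation
#'
#' Builds a deterministic fold plan, trains one network per fold and
#' evaluates every test sample with the configured prediction mode(s),
#' returning per-sample Dice reports and the pooled per-structure
#' mean and standard deviation summary.
#'
#' @param samples named or unnamed list of `hippunet_sample` objects; ids
#'   default to `subject_side`.
#' @param spec a [network_spec()].
#' @param cfg a [training_config()].
#' @param K number of folds.
#' @param modes prediction modes to evaluate (`"standard"`, `"ttbn"`).
#' @param test_transform optional function applied to each test sample
#'   before prediction (e.g. an intensity degradation for robustness
#'   experiments).
#' @param predict_fn prediction routine `function(net, sample, mode)`
#'   returning an integer label map; the default runs [predict_volume()].
#'   Substituting an oracle here exercises the harness itself.
#' @return an object of class `hippunet_cv`: `plan`, `reports` (tibble:
#'   fold, sample_id, mode, structure, dice), `summary` (per mode and
#'   structure), and the per-fold fits.
#' @export
run_crossval <- function(samples, spec, cfg = training_config(), K = 5L,
                         modes = "standard", test_transform = NULL,
                         predict_fn = NULL) {
  ids <- names(samples) %||% vapply(samples, function(s)
    paste(s$subject %||% "s", s$side %||% "x", sep = "_"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  names(samples) <- ids
  plan <- make_folds(ids, K = K, seed = cfg$seed)
  predict_fn <- predict_fn %||% function(net, sample, mode)
    predict_volume(net, sample$image, mode = mode, argmax = TRUE)
  reports <- list()
  fits <- list()
  for (k in seq_len(attr(plan, "K"))) {
    fp <- plan[plan$fold == k, ]
    if (!any(fp$role == "test")) stop("fold ", k, " has an empty test set")
    tr <- samples[fp$sample_id[fp$role == "train"]]
    va <- samples[fp$sample_id[fp$role == "validation"]]
    te <- samples[fp$sample_id[fp$role == "test"]]
    fit <- train_network(spec, unname(tr), cfg, validation = unname(va))
    fits[[k]] <- fit
    for (id in names(te)) {
      s <- te[[id]]
      if (!is.null(test_transform)) s <- test_transform(s)
      for (mode in modes) {
        pred <- predict_fn(fit$network, s, mode)
        rep_ <- dice_report(pred, s$labels, n_classes = spec$n_classes)
        rep_$fold <- k; rep_$sample_id <- id; rep_$mode <- mode
        reports[[length(reports) + 1L]] <- rep_
      }
    }
  }
  reports <- dplyr::bind_rows(reports)
  summary <- reports |>
    dplyr::group_by(.data$mode, .data$structure) |>
    dplyr::summarise(mean = mean(.data$dice), sd = stats::sd(.data$dice),
                     n = dplyr::n(), .groups = "drop")
  structure(list(plan = plan, reports = reports, summary = summary,
                 fits = fits),
            class = "hippunet_cv")
}

#' Architecture comparison harness
#'
#' Trains and evaluates several network specifications on identical folds
#' of the same samples (for instance the deeply supervised network against
#' the classic single-head U-Net) and emits a combined per-structure
#' comparison table.
#'
#' @param samples list of `hippunet_sample` objects.
#' @param specs named list of [network_spec()] objects.
#' @param cfg a [training_config()].
#' @param K number of folds.
#' @param modes prediction modes.
#' @return tibble with columns `model`, `mode`, `structure`, `mean`, `sd`,
#'   `n`, plus the per-model `hippunet_cv` results as attribute `runs`.
#' @export
compare_architectures <- function(samples, specs, cfg = training_config(),
                                  K = 5L, modes = "standard") {
  stopifnot(!is.null(names(specs)))
  runs <- lapply(specs, function(sp)
    run_crossval(samples, sp, cfg, K = K, modes = modes))
  tab <- dplyr::bind_rows(lapply(runs, function(r) r$summary), .id = "model")
  attr(tab, "runs") <- runs
  tab
}
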
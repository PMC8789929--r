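# Shared fixtures: small phantoms, tiny network specs, and a lazily
# trained shared model reused by the expensive end-to-end checks.

small_phantom_config <- function(...) {
  phantom_config(grid = c(32L, 24L, 32L), ...)
}

tiny_spec <- function(...) {
  args <- modifyList(list(in_channels = 2, n_classes = 3, levels = 2,
                          base_filters = 4, blocks_per_level = 2,
                          dropout_rate = 0), list(...))
  do.call(network_spec, args)
}

# Samples on a 16^3 grid for fast harness tests.
fast_samples <- function(n, seed = 11, n_subfields = 2) {
  cfg <- phantom_config(grid = c(16L, 16L, 16L), n_subfields = n_subfields,
                        tube_radius = 5, arc_radius = 4, seed = seed)
  lapply(generate_phantom_set(n, cfg), zscore_normalize)
}

# One shared trained model at the reference smoke-test conditions
# (20 default phantoms, tiny 3-level network, 300 GJL steps); trained once
# per test run and reused.
.shared <- new.env(parent = emptyenv())

shared_smoke_fit <- function() {
  if (is.null(.shared$fit)) {
    cfg <- phantom_config()
    train <- lapply(generate_phantom_set(20, cfg, seed = 101), zscore_normalize)
    spec <- network_spec(levels = 3, base_filters = 8)
    tc <- training_config(loss = "gjl", epochs = 100, max_steps = 300, seed = 3)
    .shared$fit <- train_network(spec, train, tc)
  }
  .shared$fit
}

smoke_test_phantoms <- function(n = 5, seed = 999) {
  lapply(generate_phantom_set(n, phantom_config(), seed = seed),
         zscore_normalize)
}

average_dice <- function(pred, truth, n_classes = 4) {
  r <- dice_report(pred, truth, n_classes)
  r$dice[r$structure == "average"]
}

# Central-difference gradient of a scalar loss function at selected entries.
numeric_gradient <- function(fn, p, idx, h = 1e-6) {
  vapply(idx, function(ii) {
    pp <- p; pp[ii] <- p[ii] + h
    pm <- p; pm[ii] <- p[ii] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, numeric(1))
}
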
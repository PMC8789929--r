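#' Dice overlap between two label maps
#'
#' `2|A n B| / (|A| + |B|)` for the binary masks of `label` in two integer
#' label maps on the same grid.  When both masks are empty the structure is
#' agreed absent and the Dice is 1; when exactly one is empty it is 0.
#'
#' @param a,b integer 3D label maps on the same grid.
#' @param label label value to compare.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b, label) {
  if (!identical(dim(a), dim(b)))
    stop("label maps have mismatched grids")
  ma <- a == label; mb <- b == label
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' Per-structure Dice report
#'
#' Computes, for labels `1..NC-1` (background excluded), the per-structure
#' Dice between a predicted and a reference label map, their unweighted
#' mean (`average`), and the Dice of the union of all non-background labels
#' (`whole`, the whole-structure overlap).
#'
#' @param pred,truth integer 3D label maps on the same grid.
#' @param n_classes number of classes including background; defaults to
#'   `max(truth) + 1`.
#' @return a tibble of class `dice_report` with columns `structure` and
#'   `dice`.
#' @export
dice_report <- function(pred, truth, n_classes = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("label maps have mismatched grids")
  nc <- n_classes %||% (max(truth) + 1L)
  labs <- seq_len(nc - 1L)
  per <- vapply(labs, function(l) dice_coefficient(pred, truth, l), numeric(1))
  whole <- {
    ma <- pred > 0; mb <- truth > 0
    if (sum(ma) + sum(mb) == 0) 1 else 2 * sum(ma & mb) / (sum(ma) + sum(mb))
  }
  out <- tibble::tibble(
    structure = c(paste0("label", labs), "average", "whole"),
    dice = c(per, mean(per), whole))
  class(out) <- c("dice_report", class(out))
  out
}

#' Deterministic K-fold plan
#'
#' Seeded shuffle of the sample identifiers followed by a contiguous
#' partition into `K` test folds (sizes differing by at most one when `K`
#' does not divide the sample count).  Within each fold's training split,
#' the last `max(2, round(n_train / 8))` shuffled identifiers are held out
#' for validation.  Every sample is tested exactly once.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param K number of folds.
#' @param seed shuffle seed.
#' @return a tibble of class `fold_plan` with columns `fold`, `sample_id`,
#'   `role` (`train` / `validation` / `test`).
#' @export
make_folds <- function(sample_ids, K = 5L, seed = 1L) {
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  if (K > n) stop("cannot make ", K, " folds from ", n, " samples")
  shuffled <- with_seed(derive_seed(seed, 5L), sample(sample_ids))
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  bounds <- cumsum(c(0L, sizes))
  rows <- lapply(seq_len(K), function(k) {
    test <- shuffled[(bounds[k] + 1):bounds[k + 1]]
    train_all <- setdiff(shuffled, test)
    n_val <- min(max(2L, round(length(train_all) / 8)), length(train_all) - 1L)
    val <- tail(train_all, n_val)
    train <- setdiff(train_all, val)
    tibble::tibble(
      fold = k,
      sample_id = c(train, val, test),
      role = c(rep("train", length(train)), rep("validation", n_val),
               rep("test", length(test))))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "K") <- K
  attr(out, "seed") <- seed
  class(out) <- c("fold_plan", class(out))
  out
}

#' Write a fold plan as JSON
#'
#' @param plan a [make_folds()] plan.
#' @param path output path.
#' @export
write_fold_plan <- function(plan, path) {
  folds <- lapply(split(plan, plan$fold), function(f)
    lapply(split(f$sample_id, f$role), as.list))
  jsonlite::write_json(list(K = attr(plan, "K"), seed = attr(plan, "seed"),
                            folds = folds),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Aggregate Dice reports
#'
#' Pools a set of per-sample [dice_report()]s into the mean and standard
#' deviation per structure, the presentation used for cross-validated
#' results tables.
#'
#' @param reports list of `dice_report` tibbles (optionally named by
#'   sample).
#' @return tibble with columns `structure`, `mean`, `sd`, `n`.
#' @export
aggregate_dice <- function(reports) {
  dplyr::bind_rows(reports, .id = "sample") |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(mean = mean(.data$dice),
                     sd = stats::sd(.data$dice),
                     n = dplyr::n(), .groups = "drop")
}
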
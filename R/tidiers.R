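# broom-style accessors for fitted models and grids.

#' Tidy a fitted PCM model
#'
#' Returns per-feature importances (impurity importance for the random
#' forest; absolute first-layer weight sums for the MLP), largest first,
#' with the descriptor block each feature belongs to.
#'
#' @param x A fitted `pcm_model`.
#' @param ... Unused.
#' @return A tibble with `feature`, `block` (`protein` / `ligand`) and
#'   `importance`.
#' @exportS3Method generics::tidy
tidy.pcm_model <- function(x, ...) {
  imp <- switch(x$learner,
    rf = ranger::importance(x$fit),
    mlp = setNames(rowSums(abs(x$fit$W[[1]])), x$feature_names)
  )
  tibble(feature = names(imp),
         block = ifelse(startsWith(names(imp), "P_"), "protein", "ligand"),
         importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Glance at a fitted PCM model
#'
#' @param x A fitted `pcm_model`.
#' @param ... Unused.
#' @return A one-row tibble summarising the fit: learner, feature counts,
#'   training size, augmentation setting and (for the forest) the
#'   out-of-bag prediction error.
#' @exportS3Method generics::glance
glance.pcm_model <- function(x, ...) {
  tibble(
    learner = x$learner,
    n_features = length(x$feature_names),
    n_protein = length(x$protein_features),
    n_ligand = length(x$ligand_features),
    n_train = x$n_train,
    n_per_target = x$augmentation$n_per_target %||% NA_real_,
    sigma = x$augmentation$sigma %||% NA_real_,
    oob_error = if (x$learner == "rf") x$fit$prediction.error else NA_real_,
    seed = x$seed
  )
}

#' @describeIn run_grid One-row summary of the grid: dimensions and the
#'   best cell by validation ROC-AUC.
#' @param x A `pcm_grid`.
#' @exportS3Method generics::glance
glance.pcm_grid <- function(x, ...) {
  best <- attr(x, "best")
  tibble(
    n_cells = nrow(x),
    n_failed = sum(!is.na(x$error)),
    best_train_fraction = best$train_fraction %||% NA_real_,
    best_n_per_target = best$n_per_target %||% NA_real_,
    best_roc_auc = best$roc_auc %||% NA_real_
  )
}
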
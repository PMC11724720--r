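# The evaluation grid (train fraction x oversampling count) and the
# protein / ligand / combined descriptor ablation.

#' Train-fraction by oversampling evaluation grid
#'
#' Fits one model per grid cell on a fresh stratified split and evaluates it
#' on the internal validation side. The classical grid spans train fractions
#' 0.50-0.90 (step 0.05) by per-target oversampling counts 1000-5000 (step
#' 500), 81 cells; the best cell is selected by validation ROC-AUC with ties
#' broken toward the larger train fraction, then the larger oversampling
#' count.
#'
#' @param examples Assembled, labeled examples.
#' @param fractions Train fractions to evaluate.
#' @param n_values Per-target oversampling counts to evaluate.
#' @param learner `"rf"` (default) or `"mlp"`.
#' @param sigma Gaussian noise scale for augmentation.
#' @param seed Base seed; cell `r` of `repeats` uses `seed + r - 1`.
#' @param repeats Number of seeded repeats per cell (metrics averaged).
#' @param ... Further arguments passed to [fit_pcm_rf()] or [fit_pcm_mlp()]
#'   (e.g. `n_trees`).
#' @return A `pcm_grid` tibble with one row per cell: the grid coordinates,
#'   averaged metric columns and an `error` column recording any cell
#'   failure (failed cells carry NA metrics, the grid continues).
#' @export
run_grid <- function(examples,
                     fractions = seq(0.50, 0.90, by = 0.05),
                     n_values = seq(1000, 5000, by = 500),
                     learner = c("rf", "mlp"), sigma = 0.1,
                     seed = 42, repeats = 1, ...) {
  learner <- match.arg(learner)
  if (length(fractions) == 0 || length(n_values) == 0) {
    abort("the grid must contain at least one cell")
  }
  fit_fun <- if (learner == "rf") fit_pcm_rf else fit_pcm_mlp
  cells <- tidyr::expand_grid(train_fraction = fractions,
                              n_per_target = n_values)
  rows <- purrr::pmap(cells, function(train_fraction, n_per_target) {
    reps <- lapply(seq_len(repeats), function(r) {
      s <- as.integer(seed) + r - 1L
      tryCatch({
        sp <- split_examples(examples, train_fraction = train_fraction,
                             seed = s)
        model <- fit_fun(sp$train, n_per_target = n_per_target,
                         sigma = sigma, seed = s, ...)
        scores <- predict(model, sp$validation)$score
        labels <- label_to_binary(as_activity_factor(sp$validation$label))
        m <- classification_metrics(labels, scores, 0.5)
        m$error <- NA_character_
        m
      }, error = function(e) {
        tibble(roc_auc = NA_real_, accuracy = NA_real_, precision = NA_real_,
               recall = NA_real_, f1 = NA_real_, fpr = NA_real_,
               cutoff_used = 0.5, n_pos = NA_integer_, n_neg = NA_integer_,
               degenerate = NA, error = conditionMessage(e))
      })
    })
    reps <- dplyr::bind_rows(reps)
    out <- dplyr::summarise(
      reps,
      across(c("roc_auc", "accuracy", "precision", "recall", "f1", "fpr"),
             ~ mean(.x)),
      n_pos = .data$n_pos[1], n_neg = .data$n_neg[1],
      error = if (all(is.na(.data$error))) NA_character_ else
        paste(stats::na.omit(.data$error), collapse = "; ")
    )
    dplyr::bind_cols(tibble(train_fraction = train_fraction,
                            n_per_target = n_per_target), out)
  })
  grid <- dplyr::bind_rows(rows)
  grid <- dplyr::arrange(grid, .data$train_fraction, .data$n_per_target)
  class(grid) <- c("pcm_grid", class(grid))
  attr(grid, "learner") <- learner
  attr(grid, "best") <- best_grid_cell(grid)
  grid
}

# Best cell by ROC-AUC; ties toward larger train fraction then larger n.
best_grid_cell <- function(grid) {
  ok <- grid[!is.na(grid$roc_auc), , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  ok <- dplyr::arrange(ok, dplyr::desc(.data$roc_auc),
                       dplyr::desc(.data$train_fraction),
                       dplyr::desc(.data$n_per_target))
  ok[1, , drop = FALSE]
}

ablation_modes <- c("PL", "P", "L")

# Restrict an example tibble to one descriptor block.
restrict_features <- function(examples, mode) {
  nms <- names(examples)
  drop <- switch(mode,
    PL = character(0),
    P = nms[startsWith(nms, "L_")],
    L = nms[startsWith(nms, "P_")],
    abort("mode must be 'PL', 'P' or 'L'")
  )
  examples[, setdiff(nms, drop), drop = FALSE]
}

#' Descriptor-block ablation
#'
#' Refits the model using only the protein block (`"P"`), only the ligand
#' block (`"L"`) or both (`"PL"`), on a fresh stratified split, and reports
#' validation metrics. Protein descriptors alone are expected to perform
#' near chance when activity is not purely target-determined; the combined
#' blocks are the full PCM feature.
#'
#' @inheritParams run_grid
#' @param mode `"PL"`, `"P"` or `"L"`.
#' @param train_fraction,n_per_target Split and augmentation setting used
#'   for the refit.
#' @param ... Passed to the fit function.
#' @return A one-row metric tibble tagged with `mode` and the retained
#'   feature dimension.
#' @export
run_ablation <- function(examples, mode = c("PL", "P", "L"),
                         train_fraction = 0.85, n_per_target = 5000,
                         sigma = 0.1, learner = c("rf", "mlp"),
                         seed = 42, ...) {
  mode <- match.arg(mode)
  learner <- match.arg(learner)
  fit_fun <- if (learner == "rf") fit_pcm_rf else fit_pcm_mlp
  restricted <- restrict_features(examples, mode)
  sp <- split_examples(restricted, train_fraction = train_fraction,
                       seed = seed)
  model <- fit_fun(sp$train, n_per_target = n_per_target, sigma = sigma,
                   seed = seed, ...)
  scores <- predict(model, sp$validation)$score
  labels <- label_to_binary(as_activity_factor(sp$validation$label))
  m <- classification_metrics(labels, scores, 0.5)
  dplyr::mutate(m, mode = mode,
                n_features = length(feature_names_of(restricted)))
}
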
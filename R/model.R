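# The PCM classifier: a random forest over the concatenated protein + ligand
# feature vector (the shipped default), trained on an augmented,
# class-balanced set, scoring pairs with a probability in [0, 1] and mapping
# scores to tri-level activity calls.

pcm_model_version <- 1L

new_pcm_model <- function(learner, fit, examples, panel, manifest, params,
                          augmentation, standardization, seed, extra = list()) {
  feats <- feature_names_of(examples)
  structure(
    c(list(
      format_version = pcm_model_version,
      learner = learner,
      fit = fit,
      feature_names = feats,
      protein_features = feats[startsWith(feats, "P_")],
      ligand_features = feats[startsWith(feats, "L_")],
      panel = panel,
      manifest = manifest,
      align_params = params,
      augmentation = augmentation,
      standardization = standardization,
      thresholds = c(medium = 0.5, high = 0.7),
      seed = seed,
      trained_at = format(Sys.time(), tz = "UTC"),
      n_train = nrow(examples),
      data_fingerprint = rlang::hash(examples[, c("compound_id", "target_id",
                                                  "label")])
    ), extra),
    class = "pcm_model"
  )
}

#' Fit the random-forest PCM classifier
#'
#' Augments the training examples (per-target class-balanced oversampling
#' with Gaussian feature noise, see [augment_examples()]) and fits a
#' probability random forest. The returned model embeds everything needed to
#' reproduce its featurization exactly: the reference panel, the descriptor
#' manifest, the alignment parameters, the augmentation configuration and
#' the feature standardization statistics.
#'
#' @param examples Assembled, labeled training examples
#'   (see [assemble_examples()]).
#' @param panel Reference panel tibble used to featurize the examples.
#' @param manifest Ligand descriptor manifest used to featurize the examples.
#' @param params The [alignment_params()] used to featurize the examples.
#' @param n_per_target,sigma Augmentation configuration; set
#'   `n_per_target = NULL` to skip augmentation.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features sampled per split; defaults to the square root of
#'   the feature count.
#' @param max_depth Maximal tree depth; `NULL` (default) grows unlimited
#'   trees.
#' @param class_weight Optional named vector of class weights
#'   (`active` / `inactive`).
#' @param seed Integer seed controlling augmentation and tree growing.
#' @return A fitted `pcm_model`.
#' @export
fit_pcm_rf <- function(examples, panel = NULL, manifest = NULL,
                       params = alignment_params(),
                       n_per_target = 5000, sigma = 0.1,
                       n_trees = 500, mtry = NULL, max_depth = NULL,
                       class_weight = NULL, seed = 42) {
  check_number(n_trees, "n_trees", min = 1)
  check_number(seed, "seed")
  if (length(unique(examples$label)) < 2) {
    abort("training data must contain both classes")
  }
  feats <- feature_names_of(examples)
  if (length(feats) == 0) abort("examples have no feature columns")

  train <- if (!is.null(n_per_target)) {
    augment_examples(examples, n_per_target = n_per_target, sigma = sigma,
                     seed = seed)
  } else {
    examples
  }
  std <- attr(train, "standardization") %||% {
    m <- as.matrix(examples[, feats])
    list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
  }

  x <- feature_matrix(train, feats)
  y <- as_activity_factor(train$label)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees, mtry = mtry,
    max.depth = if (is.null(max_depth)) 0 else max_depth,
    probability = TRUE,
    importance = "impurity",
    class.weights = if (is.null(class_weight)) NULL else
      unname(class_weight[levels(y)]),
    seed = as.integer(seed), num.threads = 1, verbose = FALSE
  )
  new_pcm_model(
    learner = "rf", fit = fit, examples = examples,
    panel = panel, manifest = manifest, params = params,
    augmentation = list(n_per_target = n_per_target, sigma = sigma,
                        seed = seed),
    standardization = std, seed = seed,
    extra = list(rf_config = list(n_trees = n_trees, mtry = mtry,
                                  max_depth = max_depth,
                                  class_weight = class_weight))
  )
}

#' Predict activity scores for assembled examples
#'
#' @param object A fitted `pcm_model`.
#' @param newdata A tibble carrying the model's feature columns (any extra
#'   columns are ignored), e.g. from [assemble_examples()].
#' @param ... Unused.
#' @return A tibble with `score` (probability of activity in \[0, 1\]) and
#'   `level` (`high` / `medium` / `low`), one row per input row, in input
#'   order; `compound_id` and `target_id` are carried through when present.
#' @export
predict.pcm_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata, object$feature_names)
  score <- switch(object$learner,
    rf = {
      p <- predict(object$fit, data = as.data.frame(x),
                   num.threads = 1)$predictions
      unname(p[, "active"])
    },
    mlp = mlp_forward(object$fit, standardize_features(x,
                                                       object$standardization)),
    abort(paste0("unknown learner: ", object$learner))
  )
  score <- pmin(1, pmax(0, score))
  out <- tibble(score = score,
                level = activity_level(score, object$thresholds))
  id_cols <- intersect(c("compound_id", "target_id"), names(newdata))
  if (length(id_cols) > 0) {
    out <- dplyr::bind_cols(newdata[, id_cols, drop = FALSE], out)
  }
  out
}

#' @export
print.pcm_model <- function(x, ...) {
  cat("<pcm_model>", x$learner, "classifier\n")
  cat("  features:", length(x$feature_names),
      sprintf("(%d protein + %d ligand)\n", length(x$protein_features),
              length(x$ligand_features)))
  cat("  training examples:", x$n_train, "\n")
  if (!is.null(x$augmentation$n_per_target)) {
    cat("  augmentation: n_per_target =", x$augmentation$n_per_target,
        ", sigma =", x$augmentation$sigma, "\n")
  }
  cat("  thresholds: medium >", x$thresholds[["medium"]],
      ", high >", x$thresholds[["high"]], "\n")
  invisible(x)
}

#' Map activity scores to tri-level calls
#'
#' Scores above 0.7 are called `high`, scores above 0.5 and up to 0.7
#' `medium`, and scores of 0.5 or below `low`; the three levels partition
#' \[0, 1\].
#'
#' @param score Numeric scores in \[0, 1\].
#' @param thresholds Named vector with elements `medium` and `high`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
activity_level <- function(score, thresholds = c(medium = 0.5, high = 0.7)) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("scores must lie in [0, 1]")
  }
  factor(ifelse(score > thresholds[["high"]], "high",
         ifelse(score > thresholds[["medium"]], "medium", "low")),
         levels = c("low", "medium", "high"))
}

# Featurize arbitrary (compound, target) pairs with a model's provenance.
featurize_pairs <- function(model, compounds, targets) {
  if (is.null(model$panel)) {
    abort("model does not embed a reference panel; cannot featurize")
  }
  pdesc <- protein_descriptors(targets, model$panel, model$align_params)
  ldesc <- ligand_descriptors(compounds, model$manifest %||% default_manifest())
  pairs <- tidyr::expand_grid(compound_id = compounds$id,
                              target_id = targets$id)
  pairs <- dplyr::left_join(pairs, pdesc, by = "target_id")
  dplyr::left_join(pairs, ldesc, by = "compound_id")
}

#' Predict activity for compound-target pairs
#'
#' Featurizes every (compound, target) pair with the provenance embedded in
#' the model and predicts its activity score and tri-level call. Pair order
#' is compounds-major (all targets for the first compound, then the second).
#'
#' @param model A fitted `pcm_model` that embeds its reference panel.
#' @param compounds Tibble with `id` and `smiles`.
#' @param targets Tibble with `id` and `sequence`, or a character vector of
#'   panel member ids.
#' @return A tibble: `compound_id`, `target_id`, `score`, `level`.
#' @export
predict_activity <- function(model, compounds, targets) {
  if (is.character(targets)) {
    missing <- setdiff(targets, model$panel$id)
    if (length(missing) > 0) {
      abort(paste0("target id(s) not in the model panel: ",
                   paste(missing, collapse = ", ")))
    }
    targets <- model$panel[match(targets, model$panel$id), c("id", "sequence")]
  }
  feats <- featurize_pairs(model, compounds, targets)
  predict(model, feats)
}

#' Screen a compound library against a target list
#'
#' Scores every (compound, target) pair and flags positives at the chosen
#' cutoff level: level 1 (normal) calls `score > 0.5` positive, level 2
#' (strict) calls `score > 0.7` positive.
#'
#' @inheritParams predict_activity
#' @param cutoff_level 1 (normal) or 2 (strict).
#' @return A `pcm_screen` tibble: `compound_id`, `target_id`, `score`,
#'   `level`, `positive`. Use [screen_summary()] for per-target positive
#'   proportions.
#' @export
screen_compounds <- function(model, compounds, targets, cutoff_level = 1) {
  if (!cutoff_level %in% c(1, 2)) abort("cutoff_level must be 1 or 2")
  if (nrow(compounds) == 0) abort("no compounds to screen")
  res <- predict_activity(model, compounds, targets)
  cut <- if (cutoff_level == 1) model$thresholds[["medium"]] else
    model$thresholds[["high"]]
  res$positive <- res$score > cut
  attr(res, "cutoff_level") <- cutoff_level
  attr(res, "cutoff") <- cut
  class(res) <- c("pcm_screen", class(res))
  res
}

#' Per-target positive proportions of a screening run
#'
#' @param screen A `pcm_screen` tibble from [screen_compounds()].
#' @return A tibble with `target_id`, `n_compounds`, `n_positive`,
#'   `prop_positive`.
#' @export
screen_summary <- function(screen) {
  if (!inherits(screen, "pcm_screen")) {
    abort("screen must come from screen_compounds()")
  }
  dplyr::summarise(dplyr::group_by(as_tibble(screen), .data$target_id),
                   n_compounds = dplyr::n(),
                   n_positive = sum(.data$positive),
                   prop_positive = mean(.data$positive),
                   .groups = "drop")
}

#' Save or load a fitted PCM model
#'
#' The archive contains the classifier state together with its full
#' featurization provenance (panel, manifest, alignment parameters,
#' augmentation configuration, standardization statistics) and a format
#' version.
#'
#' @param model A fitted `pcm_model`.
#' @param path Destination file path (RDS).
#' @return `load_pcm_model()` returns the `pcm_model`.
#' @export
save_pcm_model <- function(model, path) {
  if (!inherits(model, "pcm_model")) abort("not a pcm_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pcm_model
#' @export
load_pcm_model <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  model <- readRDS(path)
  if (!inherits(model, "pcm_model")) abort("file does not contain a pcm_model")
  if (is.null(model$format_version) ||
      model$format_version > pcm_model_version) {
    abort("model archive has an unsupported format version")
  }
  model
}

standardize_features <- function(x, std) {
  sds <- std$sd
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(sweep(x, 2, std$mean[colnames(x)], `-`), 2, sds[colnames(x)], `/`)
}
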
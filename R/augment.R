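# Training-set augmentation: per-target, class-balanced oversampling with
# Gaussian feature noise on the synthetic rows. Noise is injected on
# z-standardized features (statistics fit on the pre-augmentation training
# set) and mapped back, so one sigma has the same meaning for every feature.

#' Oversample a training set with Gaussian feature noise
#'
#' For each target, both activity classes are resampled with replacement up
#' to `n_per_target / 2` examples each, so every target contributes
#' `n_per_target` class-balanced rows. Original rows are kept unchanged
#' (noise-free, `origin = "original"`); the resampled duplicates receive
#' i.i.d. Gaussian noise with scale `sigma` per standardized feature and are
#' marked `origin = "oversampled"`. The classical operating range is 1000 to
#' 5000 per target in steps of 500 with `sigma = 0.1`; the best published
#' setting pairs 5000 with a 0.85 training fraction.
#'
#' @param train Training examples from [assemble_examples()] /
#'   [split_examples()].
#' @param n_per_target Total rows per target after augmentation (split
#'   equally between classes).
#' @param sigma Non-negative noise scale on standardized features.
#' @param seed Integer seed.
#' @return A tibble like `train` with `origin` marking synthetic rows.
#' @export
augment_examples <- function(train, n_per_target = 5000, sigma = 0.1,
                             seed = 42) {
  check_number(n_per_target, "n_per_target", min = 2)
  check_number(sigma, "sigma", min = 0)
  check_number(seed, "seed")
  if (nrow(train) == 0) abort("empty training set")
  feats <- feature_names_of(train)
  if (length(feats) == 0) abort("train has no feature columns")
  half <- floor(n_per_target / 2)

  # class coverage and capacity checks, errors name the target
  tab <- table(train$target_id, as.character(train$label))
  for (tg in rownames(tab)) {
    present <- colnames(tab)[tab[tg, ] > 0]
    if (!all(activity_levels %in% present)) {
      abort(paste0("target '", tg, "' is missing the '",
                   setdiff(activity_levels, present)[1], "' class"))
    }
    if (any(tab[tg, ] > half)) {
      abort(paste0("n_per_target = ", n_per_target, " is below the ",
                   "existing class count for target '", tg, "'"))
    }
  }

  mu <- colMeans(as.matrix(train[, feats]))
  sd_ <- apply(as.matrix(train[, feats]), 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 0  # constant features stay noise-free

  pieces <- list(train)
  withr::with_seed(as.integer(seed), {
    for (tg in sort(unique(train$target_id))) {
      for (cl in activity_levels) {
        rows <- which(train$target_id == tg & train$label == cl)
        n_new <- half - length(rows)
        if (n_new <= 0) next
        picked <- sample(rows, n_new, replace = TRUE)
        synth <- train[picked, , drop = FALSE]
        if (sigma > 0) {
          noise <- matrix(rnorm(n_new * length(feats), sd = sigma),
                          nrow = n_new)
          noise <- sweep(noise, 2, sd_, `*`)  # back to feature scale
          synth[, feats] <- as.matrix(synth[, feats]) + noise
        }
        synth$origin <- "oversampled"
        pieces[[length(pieces) + 1]] <- synth
      }
    }
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "standardization") <- list(mean = mu, sd = sd_)
  attr(out, "panel_ids") <- attr(train, "panel_ids")
  attr(out, "manifest") <- attr(train, "manifest")
  out
}
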
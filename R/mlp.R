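# Multilayer-perceptron baseline: a fully connected feed-forward network
# (217 inputs -> 5 x 300 ReLU hidden units with dropout 0.5 -> 1 sigmoid
# output) trained with Adam on binary cross-entropy. Kept as a comparison
# learner; the random forest is the shipped default.

mlp_init <- function(input_dim, hidden_layers, hidden_units) {
  sizes <- c(input_dim, rep(hidden_units, hidden_layers), 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He-normal initialization for ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                           sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

relu <- function(m) {
  m[m < 0] <- 0
  m
}

# Forward pass without dropout (inference).
mlp_forward <- function(net, x) {
  a <- x
  L <- length(net$W)
  for (l in seq_len(L - 1)) {
    a <- relu(sweep(a %*% net$W[[l]], 2, net$b[[l]], `+`))
  }
  z <- sweep(a %*% net$W[[L]], 2, net$b[[L]], `+`)
  as.numeric(1 / (1 + exp(-z)))
}

#' Fit the multilayer-perceptron PCM baseline
#'
#' Same interface and augmentation behaviour as [fit_pcm_rf()], but trains a
#' feed-forward network: `hidden_layers` fully connected ReLU layers of
#' `hidden_units` units with inverted dropout, a single sigmoid output, Adam
#' optimization of binary cross-entropy, and early stopping on a carve-out
#' of the training set. Features are z-standardized with the statistics
#' fitted on the pre-augmentation training set (stored in the model and
#' reapplied at prediction time).
#'
#' @inheritParams fit_pcm_rf
#' @param hidden_layers Number of hidden layers (default 5).
#' @param hidden_units Units per hidden layer (default 300).
#' @param dropout Dropout rate in \[0, 1) applied after every hidden layer
#'   during training (default 0.5).
#' @param epochs Maximal training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience in epochs on the validation
#'   carve-out (10% of the training rows); set `patience = Inf` to disable.
#' @return A fitted `pcm_model` with `learner = "mlp"`.
#' @export
fit_pcm_mlp <- function(examples, panel = NULL, manifest = NULL,
                        params = alignment_params(),
                        n_per_target = 5000, sigma = 0.1,
                        hidden_layers = 5, hidden_units = 300, dropout = 0.5,
                        epochs = 200, batch_size = 64, learning_rate = 1e-3,
                        patience = 10, seed = 42) {
  check_number(hidden_layers, "hidden_layers", min = 1)
  check_number(hidden_units, "hidden_units", min = 1)
  check_number(dropout, "dropout", min = 0)
  if (dropout >= 1) abort("dropout must be in [0, 1)")
  check_number(epochs, "epochs", min = 0)
  check_number(seed, "seed")
  if (length(unique(examples$label)) < 2) {
    abort("training data must contain both classes")
  }
  feats <- feature_names_of(examples)

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
  x <- standardize_features(feature_matrix(train, feats), std)
  y <- label_to_binary(as_activity_factor(train$label))

  net <- NULL
  withr::with_seed(as.integer(seed), {
    net <- mlp_init(ncol(x), hidden_layers, hidden_units)
    L <- length(net$W)
    # Adam state
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    n <- nrow(x)
    n_val <- max(1L, floor(0.1 * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0) tr_idx <- val_idx
    best_loss <- Inf; best_net <- net; stall <- 0

    bce <- function(p, yy) {
      p <- pmin(1 - 1e-7, pmax(1e-7, p))
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    }

    if (epochs >= 1) for (epoch in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m_b <- nrow(xb)
        # forward with inverted dropout
        acts <- list(xb)
        masks <- list()
        a <- xb
        for (l in seq_len(L - 1)) {
          a <- relu(sweep(a %*% net$W[[l]], 2, net$b[[l]], `+`))
          if (dropout > 0) {
            mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout),
                           nrow = nrow(a)) / (1 - dropout)
            a <- a * mask
            masks[[l]] <- mask
          }
          acts[[l + 1]] <- a
        }
        z <- sweep(a %*% net$W[[L]], 2, net$b[[L]], `+`)
        p <- 1 / (1 + exp(-z))
        # backward (BCE + sigmoid): dL/dz = p - y
        delta <- matrix(p - yb, ncol = 1) / m_b
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in rev(seq_len(L))) {
          gW[[l]] <- crossprod(acts[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(net$W[[l]])
            if (dropout > 0) delta <- delta * masks[[l - 1]]
            delta <- delta * (acts[[l]] > 0)
          }
        }
        t_step <- t_step + 1
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          mhW <- mW[[l]] / (1 - beta1^t_step)
          vhW <- vW[[l]] / (1 - beta2^t_step)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          net$W[[l]] <- net$W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      val_loss <- bce(mlp_forward(net, x[val_idx, , drop = FALSE]),
                      y[val_idx])
      if (val_loss < best_loss - 1e-6) {
        best_loss <- val_loss; best_net <- net; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
    if (epochs >= 1 && is.finite(best_loss)) net <- best_net
  })

  new_pcm_model(
    learner = "mlp", fit = net, examples = examples,
    panel = panel, manifest = manifest, params = params,
    augmentation = list(n_per_target = n_per_target, sigma = sigma,
                        seed = seed),
    standardization = std, seed = seed,
    extra = list(mlp_config = list(
      hidden_layers = hidden_layers, hidden_units = hidden_units,
      dropout = dropout, epochs = epochs, batch_size = batch_size,
      learning_rate = learning_rate, patience = patience))
  )
}
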
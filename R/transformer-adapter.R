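#' Fine-tuning configuration
#'
#' The training recipe for the encoder-plus-linear-head classifier:
#' learning rate 3e-5, batch size 16, 4 epochs and a global gradient
#' norm cap of 1.0 by default. The `tiny_random` encoder is a frozen
#' random feature map (hashed n-gram embedding followed by a seeded
#' random projection with tanh) that exercises the full training loop
#' offline; pretrained encoder ids raise a capability error because
#' their weights are not bundled.
#'
#' @param learning_rate Step size for the head optimizer.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param grad_clip_norm Global gradient norm cap applied every step.
#' @param encoder_id `"tiny_random"` or a pretrained encoder identifier.
#' @param encoder_dim Representation width of the tiny encoder.
#' @param seed Seed for encoder projection, shuffling and init.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(learning_rate = 3e-5, batch_size = 16L,
                            epochs = 4L, grad_clip_norm = 1.0,
                            encoder_id = "tiny_random", encoder_dim = 32L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            grad_clip_norm > 0, encoder_dim >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 grad_clip_norm = grad_clip_norm,
                 encoder_id = encoder_id,
                 encoder_dim = as.integer(encoder_dim),
                 seed = seed),
            class = "finetune_config")
}

# Frozen tiny encoder: hashed 3-5-gram embedding projected through a
# seeded random matrix with tanh pooling. Deterministic per (seed, text).
tiny_encoder <- function(texts, encoder_dim, seed, input_dim = 256L) {
  emb <- embed_texts(embedding_backend(dimension = input_dim), texts)
  proj <- with_seed(seed, {
    matrix(stats::rnorm(encoder_dim * input_dim, sd = 1 / sqrt(input_dim)),
           nrow = encoder_dim)
  })
  t(tanh(proj %*% emb))  # n x encoder_dim
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Fine-tune an encoder-plus-linear-head classifier
#'
#' Trains a linear classification layer over pooled encoder
#' representations with minibatch gradient descent on the softmax
#' cross-entropy, clipping the global gradient norm at
#' `grad_clip_norm` on every step, and returns the checkpoint with the
#' best validation accuracy. The optimisation trace records the
#' pre- and post-clip gradient norm of every step so the clipping
#' invariant is directly assertable.
#'
#' @param config A [finetune_config()].
#' @param train,validation Exemplar tibbles with `text` and `category`.
#' @return A list of class `finetune_model` with `predict`-able weights,
#'   `history` (per-epoch loss/accuracy tibble) and `steps` (per-step
#'   gradient norms).
#' @export
fine_tune <- function(config, train, validation) {
  stopifnot(inherits(config, "finetune_config"))
  if (config$encoder_id != "tiny_random") {
    stop("capability error: pretrained encoder '", config$encoder_id,
         "' is not available offline; use encoder_id = 'tiny_random'",
         call. = FALSE)
  }
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  lev <- language_categories()
  H_tr <- tiny_encoder(train$text, config$encoder_dim, config$seed)
  H_va <- tiny_encoder(validation$text, config$encoder_dim, config$seed)
  y_tr <- as.integer(factor(train$category, levels = lev))
  y_va <- as.integer(factor(validation$category, levels = lev))
  n <- nrow(H_tr)
  d <- ncol(H_tr)
  k <- length(lev)

  with_seed(config$seed + 1, {
    W <- matrix(stats::rnorm(d * k, sd = 0.01), nrow = d)
    b <- rep(0, k)
    Y <- matrix(0, n, k)
    Y[cbind(seq_len(n), y_tr)] <- 1
    steps <- list()
    history <- list()
    best <- list(acc = -Inf, W = W, b = b)
    lr <- config$learning_rate
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        Hb <- H_tr[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        P <- softmax_rows(Hb %*% W + matrix(b, length(idx), k, byrow = TRUE))
        loss <- -mean(log(pmax(rowSums(P * Yb), 1e-12)))
        G <- P - Yb
        gW <- crossprod(Hb, G) / length(idx)
        gb <- colMeans(G)
        pre_norm <- sqrt(sum(gW^2) + sum(gb^2))
        scale <- if (pre_norm > config$grad_clip_norm) {
          config$grad_clip_norm / pre_norm
        } else 1
        gW <- gW * scale
        gb <- gb * scale
        post_norm <- sqrt(sum(gW^2) + sum(gb^2))
        W <- W - lr * gW
        b <- b - lr * gb
        steps[[length(steps) + 1]] <- c(epoch = epoch, loss = loss,
                                        grad_norm_pre = pre_norm,
                                        grad_norm_post = post_norm)
        losses <- c(losses, loss)
      }
      P_va <- softmax_rows(H_va %*% W + matrix(b, nrow(H_va), k, byrow = TRUE))
      acc <- mean(max.col(P_va) == y_va)
      history[[epoch]] <- c(epoch = epoch, train_loss = mean(losses),
                            val_accuracy = acc)
      if (acc >= best$acc) best <- list(acc = acc, W = W, b = b)
    }
    structure(list(config = config, W = best$W, b = best$b, levels = lev,
                   val_accuracy = best$acc,
                   history = tibble::as_tibble(do.call(rbind, history)),
                   steps = tibble::as_tibble(do.call(rbind, steps))),
              class = "finetune_model")
  })
}

#' @export
print.finetune_model <- function(x, ...) {
  cat("<finetune_model> encoder ", x$config$encoder_id, ", ",
      nrow(x$W), "-d head, best val accuracy ",
      sprintf("%.3f", x$val_accuracy), "\n", sep = "")
  invisible(x)
}

#' Predict labels from a fine-tuned model
#'
#' @param object A [fine_tune()] result.
#' @param newdata Exemplar tibble (or character vector of texts).
#' @param ... Ignored.
#' @return Character vector of predicted categories.
#' @export
predict.finetune_model <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) newdata$text else newdata
  H <- tiny_encoder(texts, object$config$encoder_dim, object$config$seed)
  P <- softmax_rows(H %*% object$W +
                      matrix(object$b, nrow(H), length(object$levels),
                             byrow = TRUE))
  object$levels[max.col(P)]
}

#' @rdname fine_tune
#' @param x A `finetune_model`.
#' @param ... Ignored.
#' @method tidy finetune_model
#' @export
tidy.finetune_model <- function(x, ...) x$history

#' @rdname fine_tune
#' @method glance finetune_model
#' @export
glance.finetune_model <- function(x, ...) {
  tibble::tibble(epochs = x$config$epochs,
                 learning_rate = x$config$learning_rate,
                 batch_size = x$config$batch_size,
                 best_val_accuracy = x$val_accuracy,
                 max_grad_norm = max(x$steps$grad_norm_post))
}

#' Sequential search over fine-tuning hyperparameters
#'
#' Evaluates candidate fine-tuning configurations (learning rate, batch
#' size, epochs) in sequence, maximizing validation accuracy, and
#' returns the best configuration together with the evaluation record.
#' The tuning objective is validation accuracy by design choice; the
#' harness accepts any scorer via `score`.
#'
#' @param candidates List of [finetune_config()] objects, or a
#'   [search_space()] over `learning_rate`, `batch_size`, `epochs` from
#'   which `budget` candidates are drawn.
#' @param train,validation Exemplar tibbles.
#' @param budget Number of configurations evaluated when drawing from a
#'   space.
#' @param seed Sampling seed.
#' @param score Function `(model) -> scalar` to maximize; defaults to
#'   the model's validation accuracy.
#' @return A list with `best_config`, `best_value`, `results` (tibble).
#' @export
tune_transformer <- function(candidates, train, validation, budget = 8,
                             seed = 1L,
                             score = function(m) m$val_accuracy) {
  if (inherits(candidates, "search_space")) {
    drawn <- with_seed(seed, sample_space(candidates, budget))
    candidates <- purrr::map(drawn, function(p) {
      do.call(finetune_config, c(p, list(seed = seed)))
    })
  }
  stopifnot(length(candidates) >= 1)
  values <- vapply(candidates, function(cfg) {
    score(fine_tune(cfg, train, validation))
  }, numeric(1))
  best <- which.max(values)
  list(best_config = candidates[[best]], best_value = values[best],
       results = tibble::tibble(candidate = seq_along(values),
                                value = values))
}
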
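#' Training configuration
#'
#' Hyperparameters of the age-range classifier. The defaults are the
#' selected values of the study design: learning rate 0.0001 decaying
#' exponentially by a factor 0.9 every 4000 steps towards an end learning
#' rate of 0, weight decay 0.0001, batch size 50. The optimizer is SGD
#' with momentum 0.9 (`"adam"` available behind the flag).
#'
#' @param learning_rate initial learning rate.
#' @param decay_rate multiplicative decay factor.
#' @param decay_steps steps per decay period; the schedule is
#'   `learning_rate * decay_rate^(step / decay_steps)`, floored at
#'   `end_learning_rate`.
#' @param end_learning_rate learning-rate floor.
#' @param weight_decay L2 penalty on convolution/dense weights.
#' @param batch_size mini-batch size.
#' @param max_steps total training steps.
#' @param checkpoint_every evaluate and record accuracies every this many
#'   steps.
#' @param momentum SGD momentum.
#' @param optimizer `"sgd"` (momentum SGD, default) or `"adam"`.
#' @param select model selection rule: `"best_val"` keeps the parameters
#'   with the highest validation accuracy seen at a checkpoint (default;
#'   selecting on the test set instead is methodologically leaky),
#'   `"last"` keeps the final parameters.
#' @param seed integer RNG seed for batching (and initialization if a spec
#'   is passed to [train_cnn()]).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, decay_rate = 0.9,
                         decay_steps = 4000, end_learning_rate = 0,
                         weight_decay = 1e-4, batch_size = 50,
                         max_steps = 1000, checkpoint_every = 100,
                         momentum = 0.9, optimizer = c("sgd", "adam"),
                         select = c("best_val", "last"), seed = 1) {
  optimizer <- match.arg(optimizer)
  select <- match.arg(select)
  stopifnot(learning_rate >= 0, decay_rate > 0, decay_steps > 0,
            batch_size >= 1, max_steps >= 1, checkpoint_every >= 1)
  structure(list(learning_rate = learning_rate, decay_rate = decay_rate,
                 decay_steps = decay_steps, end_learning_rate = end_learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 checkpoint_every = as.integer(checkpoint_every),
                 momentum = momentum, optimizer = optimizer, select = select,
                 seed = as.integer(seed)),
            class = "train_config")
}

schedule_lr <- function(config, step) {
  max(config$learning_rate * config$decay_rate^(step / config$decay_steps),
      config$end_learning_rate)
}

adam_step_layer <- function(layer, grads, lr, t, weight_decay,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (layer$type == "resblock") {
    for (i in seq_along(layer$branch)) {
      layer$branch[[i]] <- adam_step_layer(layer$branch[[i]], grads$branch[[i]],
                                           lr, t, weight_decay, beta1, beta2, eps)
    }
    if (!is.null(layer$shortcut)) {
      for (i in seq_along(layer$shortcut)) {
        layer$shortcut[[i]] <- adam_step_layer(layer$shortcut[[i]],
                                               grads$shortcut[[i]], lr, t,
                                               weight_decay, beta1, beta2, eps)
      }
    }
    return(layer)
  }
  if (is.null(grads)) return(layer)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm == "W" && weight_decay > 0) g <- g + weight_decay * layer$params[[nm]]
    m <- layer$opt[[paste0("m_", nm)]]; v <- layer$opt[[paste0("v_", nm)]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    layer$opt[[paste0("m_", nm)]] <- m
    layer$opt[[paste0("v_", nm)]] <- v
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    layer$params[[nm]] <- layer$params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  layer
}

batch_accuracy <- function(net, x, y, chunk = 100L) {
  n <- dim(x)[4]
  correct <- 0L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    logits <- net_forward(net, x[, , , s:e, drop = FALSE], train = FALSE,
                          keep = FALSE)$logits
    pred <- max.col(t(logits), ties.method = "first") - 1L
    correct <- correct + sum(pred == y[s:e])
  }
  correct / n
}

#' Train the age-range classifier
#'
#' Minimizes the softmax cross-entropy between predicted age-range
#' probabilities and labels by mini-batch gradient descent with weight
#' decay, under the exponential learning-rate schedule of
#' [train_config()]. Batches are drawn as shuffled epochs; accuracy on the
#' training and validation sets is recorded at every checkpoint, and the
#' returned model keeps the checkpointed parameters selected by
#' `config$select`. Deterministic given the config seed.
#'
#' @param net an `mps_network` from [build_network()], or a
#'   [network_spec()] (then the network is built with the config seed).
#' @param x array `c(50, 200, N)` of 8-bit training images.
#' @param y integer labels 0-4, length N.
#' @param val_x,val_y optional validation images/labels.
#' @param config a [train_config()].
#' @param verbose print checkpoint progress.
#' @return an object of class `suture_cnn`: the fitted network, config,
#'   and a `history` data.frame (step, lr, loss, train_acc, val_acc).
#' @export
train_cnn <- function(net, x, y, val_x = NULL, val_y = NULL,
                      config = train_config(), verbose = FALSE) {
  if (inherits(net, "network_spec")) net <- build_network(net, seed = config$seed)
  stopifnot(inherits(net, "mps_network"))
  n <- dim(x)[4 - (length(dim(x)) == 3)]
  xin <- as_input_tensor(x, net$spec$input_shape)
  n <- dim(xin)[4]
  y <- as.integer(y)
  if (length(y) != n) stopf("x and y disagree on the number of samples")
  if (any(y < 0) || any(y >= net$spec$classes)) stopf("labels outside 0..%d", net$spec$classes - 1)
  vin <- if (!is.null(val_x)) as_input_tensor(val_x, net$spec$input_shape) else NULL
  history <- list()
  best <- list(acc = -Inf, layers = NULL)
  with_seed(config$seed, {
    order <- sample.int(n)
    pos <- 1L
    adam_t <- 0L
    for (step in seq_len(config$max_steps)) {
      bs <- min(config$batch_size, n)
      if (pos + bs - 1L > n) { order <- sample.int(n); pos <- 1L }
      idx <- order[pos:(pos + bs - 1L)]
      pos <- pos + bs
      fw <- net_forward(net, xin[, , , idx, drop = FALSE], train = TRUE)
      net <- fw$net
      ce <- cross_entropy(fw$logits, y[idx])
      if (!is.finite(ce$loss) || any(!is.finite(fw$logits))) {
        stopf("training diverged at step %d (loss = %s); lower the learning rate",
              step, format(ce$loss))
      }
      bw <- chain_backward(net$layers, ce$dlogits, fw$caches)
      lr <- schedule_lr(config, step)
      if (config$optimizer == "sgd") {
        for (i in seq_along(net$layers)) {
          net$layers[[i]] <- sgd_step_layer(net$layers[[i]], bw$grads[[i]], lr,
                                            config$momentum, config$weight_decay)
        }
      } else {
        adam_t <- adam_t + 1L
        for (i in seq_along(net$layers)) {
          net$layers[[i]] <- adam_step_layer(net$layers[[i]], bw$grads[[i]], lr,
                                             adam_t, config$weight_decay)
        }
      }
      if (step %% config$checkpoint_every == 0 || step == config$max_steps) {
        tr_idx <- if (n > 500) sort(sample.int(n, 500)) else seq_len(n)
        tr_acc <- batch_accuracy(net, xin[, , , tr_idx, drop = FALSE], y[tr_idx])
        va_acc <- if (!is.null(vin)) batch_accuracy(net, vin, val_y) else NA_real_
        history[[length(history) + 1L]] <-
          data.frame(step = step, lr = lr, loss = ce$loss,
                     train_acc = tr_acc, val_acc = va_acc)
        if (verbose) {
          message(sprintf("step %d: loss %.4f train %.3f val %s", step, ce$loss,
                          tr_acc, ifelse(is.na(va_acc), "-", sprintf("%.3f", va_acc))))
        }
        if (config$select == "best_val" && !is.na(va_acc) && va_acc > best$acc) {
          best$acc <- va_acc
          best$layers <- net$layers
        }
      }
    }
  })
  if (config$select == "best_val" && !is.null(best$layers)) net$layers <- best$layers
  structure(list(net = net, config = config,
                 history = do.call(rbind, history),
                 classes = net$spec$classes),
            class = "suture_cnn")
}

#' @export
print.suture_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf("<suture_cnn> %d-class residual classifier, %s parameters\n",
              x$classes, format(param_count(x$net), big.mark = ",")))
  cat(sprintf("  trained %d steps (batch %d, lr %g); final train acc %.3f",
              max(h$step), x$config$batch_size, x$config$learning_rate,
              h$train_acc[nrow(h)]))
  if (!all(is.na(h$val_acc))) cat(sprintf(", best val acc %.3f", max(h$val_acc, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.suture_cnn <- function(object, ...) {
  print(object)
  cat("\nCheckpoint history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' Predict age-range probabilities for new suture images
#'
#' @param object a fitted `suture_cnn`.
#' @param newdata a 50x200 matrix or an array `c(50, 200, N)`.
#' @param type `"prob"` for the N x 5 probability matrix (rows sum to 1)
#'   or `"class"` for 0-based labels (ties towards the lowest label).
#' @param ... unused.
#' @export
predict.suture_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- net_predict(object$net, newdata)
  if (type == "prob") p$probs else p$labels
}

#' @export
plot.suture_cnn <- function(x, ...) {
  h <- x$history
  plot(h$step, h$train_acc, type = "l", ylim = c(0, 1), xlab = "training step",
       ylab = "accuracy", ...)
  if (!all(is.na(h$val_acc))) {
    graphics::lines(h$step, h$val_acc, lty = 2)
    graphics::legend("bottomright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
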
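## Bidirectional LSTM classifier for fixed-length multichannel windows.
## Implemented directly on base matrix algebra: standard LSTM cell
## (input/forget/output gates and tanh candidate), both reading directions,
## last hidden states concatenated, dense softmax head, Adam optimizer,
## inverted dropout on the recurrent output, early stopping on validation
## loss with best-weight restoration.

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_lstm_weights <- function(input_size, hidden, n_classes) {
  dir_init <- function() {
    b <- rep(0, 4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias starts open
    list(Wx = glorot(input_size, 4 * hidden),
         Wh = glorot(hidden, 4 * hidden),
         b = b)
  }
  list(fwd = dir_init(), bwd = dir_init(),
       Wd = glorot(2 * hidden, n_classes), bd = rep(0, n_classes))
}

# One direction over a list of timestep matrices (each n x D).
# Returns last hidden state and, if keep_cache, everything BPTT needs.
lstm_forward <- function(xs, par, hidden, order, keep_cache = FALSE) {
  n <- nrow(xs[[1]])
  h <- matrix(0, n, hidden); cc <- matrix(0, n, hidden)
  cache <- if (keep_cache) vector("list", length(order)) else NULL
  H <- hidden
  for (k in seq_along(order)) {
    t <- order[k]
    z <- xs[[t]] %*% par$Wx + h %*% par$Wh
    z <- sweep(z, 2, par$b, `+`)
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    if (keep_cache) {
      cache[[k]] <- list(t = t, i = i, f = f, o = o, g = g,
                         c_prev = cc, h_prev = h, tc = tanh(c_new))
    }
    cc <- c_new; h <- h_new
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(xs, par, hidden, cache, dh_last) {
  H <- hidden
  dWx <- 0 * par$Wx; dWh <- 0 * par$Wh; db <- 0 * par$b
  dh <- dh_last
  dc <- matrix(0, nrow(dh_last), H)
  for (k in rev(seq_along(cache))) {
    cv <- cache[[k]]
    do <- dh * cv$tc
    dc <- dc + dh * cv$o * (1 - cv$tc^2)
    di <- dc * cv$g
    dg <- dc * cv$i
    df <- dc * cv$c_prev
    dz <- cbind(di * cv$i * (1 - cv$i),
                df * cv$f * (1 - cv$f),
                do * cv$o * (1 - cv$o),
                dg * (1 - cv$g^2))
    dWx <- dWx + crossprod(xs[[cv$t]], dz)
    dWh <- dWh + crossprod(cv$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(par$Wh)
    dc <- dc * cv$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# segments array n x C x w -> list of w matrices n x C
split_timesteps <- function(x) {
  n <- dim(x)[1]; C <- dim(x)[2]; w <- dim(x)[3]
  lapply(seq_len(w), function(t) matrix(x[, , t], n, C))
}

network_forward <- function(xs, weights, hidden, w, dropout_mask = NULL,
                            keep_cache = FALSE) {
  fw <- lstm_forward(xs, weights$fwd, hidden, seq_len(w), keep_cache)
  bw <- lstm_forward(xs, weights$bwd, hidden, rev(seq_len(w)), keep_cache)
  hcat <- cbind(fw$h, bw$h)
  hdrop <- if (is.null(dropout_mask)) hcat else hcat * dropout_mask
  logits <- sweep(hdrop %*% weights$Wd, 2, weights$bd, `+`)
  logits <- logits - apply(logits, 1, max)
  expz <- exp(logits)
  probs <- expz / rowSums(expz)
  list(probs = probs, hdrop = hdrop, fw = fw, bw = bw)
}

adam_init <- function(weights) {
  flat <- list(weights$fwd$Wx, weights$fwd$Wh, weights$fwd$b,
               weights$bwd$Wx, weights$bwd$Wh, weights$bwd$b,
               weights$Wd, weights$bd)
  list(m = lapply(flat, function(p) 0 * p),
       v = lapply(flat, function(p) 0 * p), t = 0)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  gl <- list(grads$fwd$Wx, grads$fwd$Wh, grads$fwd$b,
             grads$bwd$Wx, grads$bwd$Wh, grads$bwd$b,
             grads$Wd, grads$bd)
  upd <- vector("list", 8)
  for (j in 1:8) {
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * gl[[j]]
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * gl[[j]]^2
    mhat <- state$m[[j]] / (1 - beta1^state$t)
    vhat <- state$v[[j]] / (1 - beta2^state$t)
    upd[[j]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  weights$fwd$Wx <- weights$fwd$Wx - upd[[1]]
  weights$fwd$Wh <- weights$fwd$Wh - upd[[2]]
  weights$fwd$b <- weights$fwd$b - upd[[3]]
  weights$bwd$Wx <- weights$bwd$Wx - upd[[4]]
  weights$bwd$Wh <- weights$bwd$Wh - upd[[5]]
  weights$bwd$b <- weights$bwd$b - upd[[6]]
  weights$Wd <- weights$Wd - upd[[7]]
  weights$bd <- weights$bd - upd[[8]]
  list(weights = weights, state = state)
}

#' Fit a bidirectional LSTM segment classifier
#'
#' A shallow bidirectional long short-term memory network: one recurrent
#' layer read in both time directions (tanh cell activation), the two final
#' hidden states concatenated, and a dense softmax output over the classes.
#' Trained with the Adam optimizer to minimize the cross-entropy between the
#' ground-truth class distribution and the softmax output, with inverted
#' dropout on the recurrent output and early stopping on validation loss
#' (best-validation weights restored). Defaults: 128 hidden units, learning
#' rate 0.001, batch size 32, at most 120 epochs, dropout 0.2, patience 10.
#'
#' @param x Training segments, array n x 7 x w (channels x time window);
#'   values are expected on the normalized [0, 1] scale.
#' @param y Class labels, length n (character or factor; at least 2 classes).
#' @param validation List with elements `x` and `y` used for early stopping.
#' @param hidden_units Recurrent units per direction.
#' @param learning_rate,batch_size,max_epochs Adam training recipe.
#' @param dropout Dropout rate on the concatenated recurrent output, in [0,1).
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param seed Integer seed; fixed seed gives identical weights and history.
#' @param verbose Print per-epoch progress.
#' @return An object of class `bilstm` with elements `weights`, `classes`,
#'   `config`, `history` (one row per epoch) and `best_epoch`.
#' @export
bilstm <- function(x, y, validation = NULL, hidden_units = 128,
                   learning_rate = 0.001, batch_size = 32, max_epochs = 120,
                   dropout = 0.2, patience = 10, seed = 1L, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_mw("training set contains a single class")
  if (dropout < 0 || dropout >= 1) stop_mw("dropout must be in [0, 1)")
  n <- dim(x)[1]; C <- dim(x)[2]; w <- dim(x)[3]
  if (length(y) != n) stop_mw("x and y disagree on the number of segments")
  if (!is.null(validation) && dim(validation$x)[3] != w) {
    stop_mw("validation window length differs from training window length")
  }
  K <- length(classes)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), match(y, classes))] <- 1
  xs <- split_timesteps(x)
  val_xs <- if (!is.null(validation)) split_timesteps(validation$x)
  val_Y <- if (!is.null(validation)) match(as.character(validation$y), classes)

  with_seed(seed, {
    weights <- init_lstm_weights(C, hidden_units, K)
    opt <- adam_init(weights)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_accuracy = numeric())
    best <- list(loss = Inf, weights = weights, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      tr_loss <- 0
      for (idx in batches) {
        bxs <- lapply(xs, function(m) m[idx, , drop = FALSE])
        bY <- Y[idx, , drop = FALSE]
        mask <- if (dropout > 0) {
          matrix(stats::rbinom(length(idx) * 2 * hidden_units, 1, 1 - dropout),
                 length(idx), 2 * hidden_units) / (1 - dropout)
        } else NULL
        fwd <- network_forward(bxs, weights, hidden_units, w, mask,
                               keep_cache = TRUE)
        p <- pmax(fwd$probs, 1e-12)
        tr_loss <- tr_loss - sum(log(p[bY == 1])) / n
        dlogits <- (fwd$probs - bY) / length(idx)
        gWd <- crossprod(fwd$hdrop, dlogits)
        gbd <- colSums(dlogits)
        dhd <- dlogits %*% t(weights$Wd)
        if (!is.null(mask)) dhd <- dhd * mask
        dfw <- dhd[, 1:hidden_units, drop = FALSE]
        dbw <- dhd[, (hidden_units + 1):(2 * hidden_units), drop = FALSE]
        grads <- list(
          fwd = lstm_backward(bxs, weights$fwd, hidden_units, fwd$fw$cache, dfw),
          bwd = lstm_backward(bxs, weights$bwd, hidden_units, fwd$bw$cache, dbw),
          Wd = gWd, bd = gbd
        )
        st <- adam_step(weights, grads, opt, learning_rate)
        weights <- st$weights; opt <- st$state
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(validation)) {
        vf <- network_forward(val_xs, weights, hidden_units, w)
        vp <- pmax(vf$probs, 1e-12)
        val_loss <- -mean(log(vp[cbind(seq_along(val_Y), val_Y)]))
        val_acc <- mean(max.col(vf$probs) == val_Y)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss,
        val_loss = val_loss, val_accuracy = val_acc))
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f  val loss %s  val acc %s",
                        epoch, tr_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
      if (!is.null(validation)) {
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, weights = weights, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else {
        best <- list(loss = tr_loss, weights = weights, epoch = epoch)
      }
    }
    structure(list(
      weights = best$weights, classes = classes,
      config = list(hidden_units = hidden_units, learning_rate = learning_rate,
                    batch_size = batch_size, max_epochs = max_epochs,
                    dropout = dropout, patience = patience, seed = seed,
                    input_channels = C, window = w),
      history = history, best_epoch = best$epoch
    ), class = "bilstm")
  })
}

#' Predict from a fitted BiLSTM
#'
#' @param object A `bilstm` object.
#' @param x Segments, array n x channels x w matching the training shape.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Character vector of labels or an n x K probability matrix.
#' @export
predict.bilstm <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (dim(x)[3] != object$config$window) {
    stop_mw("segment window %d does not match the fitted window %d",
            dim(x)[3], object$config$window)
  }
  xs <- split_timesteps(x)
  fwd <- network_forward(xs, object$weights, object$config$hidden_units,
                         object$config$window)
  colnames(fwd$probs) <- object$classes
  if (type == "prob") return(fwd$probs)
  object$classes[max.col(fwd$probs)]
}

#' @export
print.bilstm <- function(x, ...) {
  cat(sprintf("BiLSTM classifier: %d hidden units/direction, %d classes, window %d\n",
              x$config$hidden_units, length(x$classes), x$config$window))
  cat(sprintf("  trained %d epochs (best validation at epoch %d)\n",
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.bilstm <- function(object, ...) {
  h <- object$history
  cat("BiLSTM training summary\n")
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  epochs run: %d; best epoch: %d\n", nrow(h), object$best_epoch))
  if (any(!is.na(h$val_loss))) {
    cat(sprintf("  best validation loss: %.4f; accuracy there: %.3f\n",
                min(h$val_loss, na.rm = TRUE),
                h$val_accuracy[which.min(h$val_loss)]))
  }
  invisible(object$history)
}

#' @export
coef.bilstm <- function(object, ...) object$weights

#' Plot the training history of a BiLSTM
#'
#' @param x A `bilstm` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bilstm <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", col = "steelblue",
                 ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE), ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, col = "firebrick")
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("steelblue", "firebrick"), bty = "n")
  }
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Seeded random hyperparameter search
#'
#' Draws configurations uniformly from the supplied ranges, trains each on
#' the dataset's train partition and scores it on validation accuracy.
#'
#' @param dataset A `segment_dataset`.
#' @param n_draws Number of configurations to try.
#' @param lr_range Log-uniform learning-rate range.
#' @param dropout_range Uniform dropout range.
#' @param hidden_choices Candidate hidden-unit counts.
#' @param seed Integer seed.
#' @param ... Further fixed arguments passed to [bilstm()].
#' @return Data frame of configurations and validation accuracies, best first.
#' @export
random_search <- function(dataset, n_draws = 5, lr_range = c(1e-4, 1e-2),
                          dropout_range = c(0, 0.5),
                          hidden_choices = c(32, 64, 128), seed = 1L, ...) {
  tr <- partition_xy(dataset, "train")
  va <- partition_xy(dataset, "validation")
  draws <- with_seed(seed, data.frame(
    learning_rate = exp(stats::runif(n_draws, log(lr_range[1]), log(lr_range[2]))),
    dropout = stats::runif(n_draws, dropout_range[1], dropout_range[2]),
    hidden_units = sample(hidden_choices, n_draws, replace = TRUE)
  ))
  draws$val_accuracy <- NA_real_
  for (i in seq_len(n_draws)) {
    fit <- bilstm(tr$x, tr$y, validation = list(x = va$x, y = va$y),
                  hidden_units = draws$hidden_units[i],
                  learning_rate = draws$learning_rate[i],
                  dropout = draws$dropout[i],
                  seed = seed + i, ...)
    draws$val_accuracy[i] <- mean(predict(fit, va$x) == va$y)
  }
  draws[order(-draws$val_accuracy), ]
}
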
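# loss of the whole network for the finite-difference gradient check
net_loss <- function(weights, xs, Y, hidden, w) {
  fwd <- moodwear:::network_forward(xs, weights, hidden, w)
  p <- pmax(fwd$probs, 1e-12)
  -sum(log(p[Y == 1])) / nrow(Y)
}

test_that("backpropagation gradients match finite differences", {
  set.seed(99)
  n <- 5; C <- 4; w <- 6; H <- 3; K <- 3
  x <- array(rnorm(n * C * w), dim = c(n, C, w))
  xs <- moodwear:::split_timesteps(x)
  y <- sample(K, n, replace = TRUE)
  Y <- matrix(0, n, K); Y[cbind(1:n, y)] <- 1
  weights <- moodwear:::init_lstm_weights(C, H, K)

  fwd <- moodwear:::network_forward(xs, weights, H, w, keep_cache = TRUE)
  dlogits <- (fwd$probs - Y) / n
  dhd <- dlogits %*% t(weights$Wd)
  grads <- list(
    fwd = moodwear:::lstm_backward(xs, weights$fwd, H, fwd$fw$cache,
                                   dhd[, 1:H, drop = FALSE]),
    bwd = moodwear:::lstm_backward(xs, weights$bwd, H, fwd$bw$cache,
                                   dhd[, (H + 1):(2 * H), drop = FALSE]),
    Wd = crossprod(fwd$hdrop, dlogits), bd = colSums(dlogits)
  )
  eps <- 1e-6
  num_grad <- function(getter, setter, idx) {
    wp <- setter(weights, getter(weights)[idx] + eps, idx)
    wm <- setter(weights, getter(weights)[idx] - eps, idx)
    (net_loss(wp, xs, Y, H, w) - net_loss(wm, xs, Y, H, w)) / (2 * eps)
  }
  paths <- list(
    list(get = function(w) w$fwd$Wx,
         set = function(w, v, i) { w$fwd$Wx[i] <- v; w },
         ana = grads$fwd$Wx),
    list(get = function(w) w$fwd$Wh,
         set = function(w, v, i) { w$fwd$Wh[i] <- v; w },
         ana = grads$fwd$Wh),
    list(get = function(w) w$fwd$b,
         set = function(w, v, i) { w$fwd$b[i] <- v; w },
         ana = grads$fwd$b),
    list(get = function(w) w$bwd$Wx,
         set = function(w, v, i) { w$bwd$Wx[i] <- v; w },
         ana = grads$bwd$Wx),
    list(get = function(w) w$bwd$Wh,
         set = function(w, v, i) { w$bwd$Wh[i] <- v; w },
         ana = grads$bwd$Wh),
    list(get = function(w) w$Wd,
         set = function(w, v, i) { w$Wd[i] <- v; w },
         ana = grads$Wd),
    list(get = function(w) w$bd,
         set = function(w, v, i) { w$bd[i] <- v; w },
         ana = grads$bd)
  )
  set.seed(5)
  for (p in paths) {
    for (idx in sample(length(p$ana), min(5, length(p$ana)))) {
      expect_equal(num_grad(p$get, p$set, idx), p$ana[idx], tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  arr <- make_arrays(12, w = 8)
  va <- make_arrays(6, w = 8, seed = 2)
  fit1 <- bilstm(arr$x, arr$y, validation = list(x = va$x, y = va$y),
                 hidden_units = 8, max_epochs = 5, seed = 7)
  fit2 <- bilstm(arr$x, arr$y, validation = list(x = va$x, y = va$y),
                 hidden_units = 8, max_epochs = 5, seed = 7)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(predict(fit1, va$x, type = "prob"),
                   predict(fit2, va$x, type = "prob"))
})

test_that("degenerate inputs are rejected", {
  arr <- make_arrays(10, w = 4)
  expect_error(bilstm(arr$x, rep("A", 30)), "single class")
  expect_error(bilstm(arr$x, arr$y, dropout = 1), "dropout")
  expect_error(bilstm(arr$x, arr$y[-1]), "disagree")
  va <- make_arrays(5, w = 8)
  expect_error(bilstm(arr$x, arr$y, validation = list(x = va$x, y = va$y)),
               "window length")
  fit <- bilstm(arr$x, arr$y, hidden_units = 4, max_epochs = 2, seed = 1)
  expect_error(predict(fit, va$x), "window")
})

test_that("a separable three-class problem is learned to high accuracy", {
  sm <- fit_small_model()
  acc <- mean(predict(sm$fit, sm$test$x) == sm$test$y)
  expect_gte(acc, 0.9)
  probs <- predict(sm$fit, sm$test$x, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_identical(colnames(probs), sort(unique(sm$test$y)))
})

test_that("early stopping restores the best-validation weights", {
  arr <- make_arrays(15, w = 8, shift = 0.6)
  va <- make_arrays(8, w = 8, shift = 0.6, seed = 3)
  fit <- bilstm(arr$x, arr$y, validation = list(x = va$x, y = va$y),
                hidden_units = 8, max_epochs = 60, patience = 4, seed = 2)
  h <- fit$history
  expect_lte(nrow(h), 60)
  expect_equal(fit$best_epoch, which.min(h$val_loss))
})

test_that("evaluation metrics behave on perfect, balanced and random input", {
  # perfect predictions
  y <- rep(c("A", "B", "C"), each = 10)
  probs <- matrix(0.001, 30, 3, dimnames = list(NULL, c("A", "B", "C")))
  probs[cbind(1:30, match(y, c("A", "B", "C")))] <- 0.998
  r <- eval_report(y, y, probs, c("A", "B", "C"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$micro$f1, 1)
  expect_equal(unname(r$auroc), rep(1, 3))
  # balanced set: micro precision = recall = F1 = accuracy
  set.seed(8)
  pred <- sample(c("A", "B", "C"), 30, replace = TRUE)
  r2 <- eval_report(pred, y)
  expect_equal(r2$micro$precision, r2$accuracy)
  expect_equal(r2$micro$recall, r2$accuracy)
  expect_equal(r2$micro$f1, r2$accuracy)
  # random scores: one-vs-rest AUROC near 0.5
  set.seed(9)
  n <- 3000
  y3 <- sample(c("A", "B", "C"), n, replace = TRUE)
  p3 <- matrix(runif(3 * n), n, 3); p3 <- p3 / rowSums(p3)
  colnames(p3) <- c("A", "B", "C")
  r3 <- eval_report(colnames(p3)[max.col(p3)], y3, p3)
  expect_true(all(abs(r3$auroc - 0.5) < 0.05))
  # confusion rows sum to per-class counts
  expect_equal(unname(rowSums(r3$confusion)), as.vector(table(y3)))
})

test_that("evaluation requires every class in the test set", {
  sm <- fit_small_model()
  keep <- sm$test$y != "C1"
  expect_error(evaluate_model(sm$fit, sm$test$x[keep, , , drop = FALSE],
                              sm$test$y[keep]), "C1")
})

test_that("random search returns seeded, ranked configurations", {
  arr <- make_arrays(30, w = 4)
  pool <- list(segments = arr$x, labels = arr$y,
               sessions = rep("s", 90), subjects = rep("p", 90))
  ds <- make_partitions(pool, test_per_class = 4, seed = 1)
  rs <- random_search(ds, n_draws = 2, hidden_choices = c(4, 8),
                      max_epochs = 3, seed = 1)
  expect_equal(nrow(rs), 2)
  expect_true(all(diff(rs$val_accuracy) <= 0))
  rs2 <- random_search(ds, n_draws = 2, hidden_choices = c(4, 8),
                       max_epochs = 3, seed = 1)
  expect_equal(rs$val_accuracy, rs2$val_accuracy)
})
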
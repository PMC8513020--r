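# Minimal multilayer perceptron classifier: tanh hidden layers, softmax
# output, cross-entropy + L2 penalty, trained with mini-batch Adam at a
# constant learning rate. Inputs are standardized internally. This is the
# fitting engine behind the ANN model specification (three hidden layers of
# 100 units).

mlp_fit <- function(x, y, hidden = c(100, 100, 100), alpha = 1e-4,
                    learning_rate = 1e-3, max_iter = 1000,
                    batch_size = 200, tol = 1e-4, n_iter_no_change = 10,
                    seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  n <- nrow(x); k <- length(classes)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  yi <- matrix(0, n, k); yi[cbind(seq_len(n), as.integer(y))] <- 1

  sizes <- c(ncol(x), hidden, k)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      matrix(runif(sizes[l] * sizes[l + 1], -r, r), sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(z) z * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_loss <- Inf; stalled <- 0L
    bs <- min(batch_size, n)

    for (it in seq_len(max_iter)) {
      perm <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- xs[idx, , drop = FALSE]; yb <- yi[idx, , drop = FALSE]
        m <- length(idx)
        # forward
        act <- vector("list", L + 1L); act[[1]] <- xb
        for (l in seq_len(L - 1L)) {
          act[[l + 1]] <- tanh(sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+"))
        }
        z <- sweep(act[[L]] %*% W[[L]], 2, b[[L]], "+")
        z <- z - apply(z, 1, max)
        ez <- exp(z); p <- ez / rowSums(ez)
        epoch_loss <- epoch_loss - sum(yb * log(pmax(p, 1e-12)))
        # backward
        delta <- (p - yb) / m
        for (l in rev(seq_len(L))) {
          gW <- crossprod(act[[l]], delta) + alpha * W[[l]] / m
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (1 - act[[l]]^2)
          }
          step_l <- step + 1L
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^step_l); vhW <- vW[[l]] / (1 - beta2^step_l)
          mhb <- mb[[l]] / (1 - beta1^step_l); vhb <- vb[[l]] / (1 - beta2^step_l)
          W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
        step <- step + 1L
      }
      epoch_loss <- epoch_loss / n
      if (epoch_loss > best_loss - tol) stalled <- stalled + 1L else stalled <- 0L
      best_loss <- min(best_loss, epoch_loss)
      if (stalled >= n_iter_no_change) break
    }
    structure(list(W = W, b = b, classes = classes, center = ctr, scale = scl,
                   n_iter = it, loss = epoch_loss),
              class = "gf_mlp")
  })
}

#' @export
predict.gf_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  a <- xs
  L <- length(object$W)
  for (l in seq_len(L - 1L)) {
    a <- tanh(sweep(a %*% object$W[[l]], 2, object$b[[l]], "+"))
  }
  z <- sweep(a %*% object$W[[L]], 2, object$b[[L]], "+")
  z <- z - apply(z, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}
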
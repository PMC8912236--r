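# Minimal feed-forward network for the ANN model family: one hidden layer
# of rectified-linear units, a sigmoid output, binary cross-entropy loss,
# Adam updates. Written directly in matrix algebra; deterministic under a
# fixed seed.

mlp_fit <- function(x, y, hidden = 100, epochs = 30, batch_size = 16,
                    learning_rate = 1e-3, seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  set.seed(stage_seed(seed, "mlp"))
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd); sd[sd == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")

  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(pars, function(p) p * 0); v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- xs[idx, , drop = FALSE]; yb <- y[idx]; nb <- length(idx)
      z1 <- sweep(xb %*% pars$W1, 2, pars$b1, "+")
      a1 <- pmax(z1, 0)
      z2 <- as.numeric(a1 %*% pars$W2) + pars$b2
      prob <- 1 / (1 + exp(-z2))
      # BCE gradient at the sigmoid input
      dz2 <- (prob - yb) / nb
      g <- list(W2 = t(a1) %*% dz2, b2 = sum(dz2),
                W1 = NULL, b1 = NULL)
      da1 <- outer(dz2, as.numeric(pars$W2))
      dz1 <- da1 * (z1 > 0)
      g$W1 <- t(xb) %*% dz1
      g$b1 <- colSums(dz1)
      t <- t + 1
      for (nm in names(pars)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t)
        vhat <- v[[nm]] / (1 - beta2^t)
        pars[[nm]] <- pars[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(pars = pars, center = mu, scale = sd,
                 hidden = hidden, epochs = epochs), class = "ventsig_mlp")
}

mlp_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  a1 <- pmax(sweep(xs %*% fit$pars$W1, 2, fit$pars$b1, "+"), 0)
  z2 <- as.numeric(a1 %*% fit$pars$W2) + fit$pars$b2
  1 / (1 + exp(-z2))
}
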
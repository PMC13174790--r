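# Monotone posterior neural network.
#
# A 1-input network with two hidden tanh layers of width 16 and a sigmoid
# output. All weight matrices are re-parameterized through softplus so the
# effective weights are non-negative; combined with monotone activations
# this guarantees the score-to-posterior map is non-decreasing. Trained by
# full-batch Adam on the binomial negative log-likelihood with a seeded 20%
# validation split and early stopping.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

nn_init <- function(h = 16L, seed = 1L) {
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(h, -1, 0.5), 1, h),
    b1 = stats::rnorm(h, 0, 0.5),
    W2 = matrix(stats::rnorm(h * h, -2, 0.5), h, h),
    b2 = stats::rnorm(h, 0, 0.5),
    W3 = matrix(stats::rnorm(h, -2, 0.5), h, 1),
    b3 = 0))
}

nn_forward <- function(par, x) {
  X <- matrix(x, ncol = 1)
  W1p <- softplus(par$W1); W2p <- softplus(par$W2); W3p <- softplus(par$W3)
  a1 <- X %*% W1p + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE)
  h1 <- tanh(a1)
  a2 <- h1 %*% W2p + matrix(par$b2, nrow(X), length(par$b2), byrow = TRUE)
  h2 <- tanh(a2)
  z <- drop(h2 %*% W3p) + par$b3
  list(p = stats::plogis(z), h1 = h1, h2 = h2, X = X,
       W1p = W1p, W2p = W2p, W3p = W3p)
}

nn_grad <- function(par, fw, y) {
  n <- length(y)
  dz <- (fw$p - y) / n
  dW3p <- t(fw$h2) %*% matrix(dz, ncol = 1)
  db3 <- sum(dz)
  dh2 <- matrix(dz, ncol = 1) %*% t(fw$W3p)
  da2 <- dh2 * (1 - fw$h2^2)
  dW2p <- t(fw$h1) %*% da2
  db2 <- colSums(da2)
  dh1 <- da2 %*% t(fw$W2p)
  da1 <- dh1 * (1 - fw$h1^2)
  dW1p <- t(fw$X) %*% da1
  db1 <- colSums(da1)
  # chain through the softplus re-parameterization
  list(W1 = dW1p * stats::plogis(par$W1), b1 = db1,
       W2 = dW2p * stats::plogis(par$W2), b2 = db2,
       W3 = dW3p * stats::plogis(par$W3), b3 = db3)
}

nn_nll <- function(p, y) {
  p <- clamp01(p, 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_mono_post_nn <- function(data, epochs = 300L, lr = 0.05, seed = 1L,
                             patience = 30L, hidden = 16L) {
  d <- labeled_xy(data)
  n <- length(d$x)
  idx_val <- with_seed(child_seed(seed, 7L),
                       sample(n, size = max(1L, floor(0.2 * n))))
  xt <- d$x[-idx_val]; yt <- d$y[-idx_val]
  xv <- d$x[idx_val]; yv <- d$y[idx_val]
  par <- nn_init(hidden, seed = seed)
  m <- lapply(par, function(p) p * 0); v <- m
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  best <- list(par = par, loss = Inf, epoch = 0L)
  for (t in seq_len(epochs)) {
    fw <- nn_forward(par, xt)
    g <- nn_grad(par, fw, yt)
    for (k in names(par)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^t); vhat <- v[[k]] / (1 - b2^t)
      par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + epsa)
    }
    if (t %% 5 == 0 || t == epochs) {
      vloss <- nn_nll(nn_forward(par, xv)$p, yv)
      if (vloss < best$loss - 1e-6) best <- list(par = par, loss = vloss, epoch = t)
      else if (t - best$epoch >= patience) break
    }
  }
  final <- best$par
  function(s) nn_forward(final, s)$p
}
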
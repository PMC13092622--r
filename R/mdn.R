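# Mixture density network q(y | x): a two-hidden-layer tanh network whose
# output parameterizes a K-component diagonal Gaussian mixture over y.
# Trained by minimizing the negative log-likelihood with Adam. All in base
# R matrix algebra; gradients are exact (checked against finite differences
# in the test suite).

LOGSIG_MIN <- -7
LOGSIG_MAX <- 7

mdn_init <- function(d_in, d_out, n_comp = 10, n_hidden = 64) {
  d3 <- n_comp + 2 * n_comp * d_out
  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  list(W1 = init(d_in, n_hidden), b1 = numeric(n_hidden),
       W2 = init(n_hidden, n_hidden), b2 = numeric(n_hidden),
       W3 = init(n_hidden, d3) * 0.1, b3 = numeric(d3),
       d_in = d_in, d_out = d_out, K = n_comp, H = n_hidden)
}

# forward pass; returns hidden activations and mixture parameters
mdn_forward <- function(net, X) {
  h1 <- tanh(sweep(X %*% net$W1, 2, net$b1, "+"))
  h2 <- tanh(sweep(h1 %*% net$W2, 2, net$b2, "+"))
  out <- sweep(h2 %*% net$W3, 2, net$b3, "+")
  K <- net$K; d <- net$d_out
  list(h1 = h1, h2 = h2,
       logits = out[, seq_len(K), drop = FALSE],
       mu = out[, K + seq_len(K * d), drop = FALSE],
       logsig = pmin(pmax(out[, K + K * d + seq_len(K * d), drop = FALSE],
                          LOGSIG_MIN), LOGSIG_MAX),
       raw_logsig = out[, K + K * d + seq_len(K * d), drop = FALSE])
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# per-row log q(y | x); fw is an mdn_forward result for the same rows
mdn_loglik_rows <- function(net, fw, Y) {
  K <- net$K; d <- net$d_out
  N <- nrow(Y)
  g <- matrix(0, N, K)
  for (k in seq_len(K)) {
    cols <- (k - 1) * d + seq_len(d)
    z <- (Y - fw$mu[, cols, drop = FALSE]) / exp(fw$logsig[, cols, drop = FALSE])
    g[, k] <- rowSums(-0.5 * log(2 * pi) - fw$logsig[, cols, drop = FALSE] -
                        0.5 * z^2)
  }
  u <- fw$logits + g
  logsumexp_rows(u) - logsumexp_rows(fw$logits)
}

# loss and exact gradients for one batch
mdn_loss_grad <- function(net, X, Y) {
  fw <- mdn_forward(net, X)
  K <- net$K; d <- net$d_out; N <- nrow(X)
  g <- matrix(0, N, K)
  zs <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- (k - 1) * d + seq_len(d)
    z <- (Y - fw$mu[, cols, drop = FALSE]) / exp(fw$logsig[, cols, drop = FALSE])
    zs[[k]] <- z
    g[, k] <- rowSums(-0.5 * log(2 * pi) - fw$logsig[, cols, drop = FALSE] -
                        0.5 * z^2)
  }
  u <- fw$logits + g
  ll <- logsumexp_rows(u) - logsumexp_rows(fw$logits)
  loss <- -mean(ll)
  r <- exp(u - logsumexp_rows(u))          # responsibilities
  pi_k <- exp(fw$logits - logsumexp_rows(fw$logits))
  d_logits <- (pi_k - r) / N
  d_mu <- matrix(0, N, K * d)
  d_logsig <- matrix(0, N, K * d)
  for (k in seq_len(K)) {
    cols <- (k - 1) * d + seq_len(d)
    sig <- exp(fw$logsig[, cols, drop = FALSE])
    d_mu[, cols] <- -r[, k] * zs[[k]] / sig / N
    d_logsig[, cols] <- -r[, k] * (zs[[k]]^2 - 1) / N
  }
  # clamp pass-through only inside the active range
  d_logsig[fw$raw_logsig <= LOGSIG_MIN | fw$raw_logsig >= LOGSIG_MAX] <- 0
  d_out <- cbind(d_logits, d_mu, d_logsig)
  d_h2 <- (d_out %*% t(net$W3)) * (1 - fw$h2^2)
  d_h1 <- (d_h2 %*% t(net$W2)) * (1 - fw$h1^2)
  list(loss = loss,
       grads = list(W1 = t(X) %*% d_h1, b1 = colSums(d_h1),
                    W2 = t(fw$h1) %*% d_h2, b2 = colSums(d_h2),
                    W3 = t(fw$h2) %*% d_out, b3 = colSums(d_out)))
}

adam_init <- function(net) {
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3")
  list(m = lapply(net[nm], function(w) w * 0),
       v = lapply(net[nm], function(w) w * 0), t = 0)
}

adam_step <- function(net, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(st$m)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = st)
}

# full training loop with validation split and early stopping
mdn_train <- function(X, Y, n_comp = 10, n_hidden = 64, batch = 256,
                      lr = 1e-3, max_epochs = 500, patience = 20,
                      val_frac = 0.1, verbose = FALSE) {
  N <- nrow(X)
  stopifnot(nrow(Y) == N, N >= 20)
  net <- mdn_init(ncol(X), ncol(Y), n_comp, n_hidden)
  n_val <- max(1, round(val_frac * N))
  idx <- sample.int(N)
  vi <- idx[seq_len(n_val)]
  ti <- idx[-seq_len(n_val)]
  Xt <- X[ti, , drop = FALSE]; Yt <- Y[ti, , drop = FALSE]
  Xv <- X[vi, , drop = FALSE]; Yv <- Y[vi, , drop = FALSE]
  st <- adam_init(net)
  best <- list(net = net, val = Inf, epoch = 0)
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(nrow(Xt))
    tr_loss <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1, length(ord))]
      lg <- mdn_loss_grad(net, Xt[bi, , drop = FALSE], Yt[bi, , drop = FALSE])
      if (!is.finite(lg$loss)) stop("divergent loss at epoch ", ep)
      up <- adam_step(net, lg$grads, st, lr)
      net <- up$net; st <- up$state
      tr_loss <- tr_loss + lg$loss; nb <- nb + 1
    }
    val <- -mean(mdn_loglik_rows(net, mdn_forward(net, Xv), Yv))
    hist <- rbind(hist, data.frame(epoch = ep, train = tr_loss / nb, val = val))
    if (val < best$val - 1e-5) best <- list(net = net, val = val, epoch = ep)
    if (ep - best$epoch >= patience) break
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d train %.4f val %.4f", ep, tr_loss / nb, val))
  }
  list(net = best$net, history = hist, best_epoch = best$epoch,
       best_val = best$val)
}

# mixture parameters for a single conditioning vector x; column layout of
# fw$mu is (k-1)*d + j
mdn_components_at <- function(net, x) {
  fw <- mdn_forward(net, matrix(x, nrow = 1))
  K <- net$K; d <- net$d_out
  mu <- matrix(drop(fw$mu), K, d, byrow = TRUE)
  sig <- matrix(drop(exp(fw$logsig)), K, d, byrow = TRUE)
  list(pi = drop(exp(fw$logits - logsumexp_rows(fw$logits))), mu = mu,
       sig = sig)
}

# draw n samples from q(. | x)
mdn_sample_at <- function(net, x, n) {
  cm <- mdn_components_at(net, x)
  comp <- sample.int(net$K, n, replace = TRUE, prob = cm$pi)
  eps <- matrix(rnorm(n * net$d_out), n, net$d_out)
  cm$mu[comp, , drop = FALSE] + cm$sig[comp, , drop = FALSE] * eps
}

# log q(y | x) for many y at one x
mdn_logdens_at <- function(net, x, Y) {
  cm <- mdn_components_at(net, x)
  N <- nrow(Y)
  u <- matrix(0, N, net$K)
  for (k in seq_len(net$K)) {
    z <- sweep(sweep(Y, 2, cm$mu[k, ], "-"), 2, cm$sig[k, ], "/")
    u[, k] <- log(cm$pi[k]) +
      rowSums(-0.5 * log(2 * pi) - rep(log(cm$sig[k, ]), each = N) - 0.5 * z^2)
  }
  logsumexp_rows(u)
}

# gradient of log q(y | x) with respect to y (rows of Y)
mdn_grad_y_at <- function(net, x, Y) {
  cm <- mdn_components_at(net, x)
  N <- nrow(Y)
  u <- matrix(0, N, net$K)
  for (k in seq_len(net$K)) {
    z <- sweep(sweep(Y, 2, cm$mu[k, ], "-"), 2, cm$sig[k, ], "/")
    u[, k] <- log(cm$pi[k]) +
      rowSums(-0.5 * log(2 * pi) - rep(log(cm$sig[k, ]), each = N) - 0.5 * z^2)
  }
  r <- exp(u - logsumexp_rows(u))
  gr <- matrix(0, N, net$d_out)
  for (k in seq_len(net$K)) {
    dk <- sweep(sweep(-sweep(Y, 2, cm$mu[k, ], "-"), 2, cm$sig[k, ]^2, "/"),
                1, r[, k], "*")
    gr <- gr + dk
  }
  gr
}
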
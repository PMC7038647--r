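# Batched forward/backward passes and the Adam optimiser for the attention
# network. The network has four stages:
#
#   embed:      x_hat_j^(i) = x_ji * e_i                  (no parameters)
#   represent:  f_x = tanh(x_hat W_x + b_x)               (m -> p, one layer)
#   attention:  f_a = tanh(x_hat W_a1 + b_a1) w_a2 + b_a2 (m -> 1, one hidden
#               layer); beta_j = softmax(alpha_j) over features
#   classify:   f_y = sigmoid(relu(BN(xbar W_y1 + b_y1)) w_y2 + b_y2)
#
# The sample representation is xbar_j = sum_i beta_ji f_x(x_hat_j^(i)).
# Attention is self-attention: alpha_ji depends only on feature i's own
# embedded value, with weights shared across features, so the whole batch can
# be flattened to (n*d)-row matrices (sample index fastest). Dropout is
# inverted (masks pre-divided by the keep probability) and applied to the
# tanh outputs of f_x, the hidden layer of f_a, and the ReLU layer of f_y.
# Batch normalisation uses biased batch variance during training and running
# estimates at evaluation.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

nn_init_params <- function(m, p, ha, hy) {
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  list(
    Wx = g(m, p), bx = numeric(p),
    Wa1 = g(m, ha), ba1 = numeric(ha),
    wa2 = rnorm(ha, sd = 1 / sqrt(ha)), ba2 = 0,
    Wy1 = g(p, hy), by1 = numeric(hy),
    gamma = rep(1, hy), delta = numeric(hy),
    wy2 = rnorm(hy, sd = 1 / sqrt(hy)), by2 = 0
  )
}

.softmax_rows <- function(a) {
  amax <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  e <- exp(a - amax)           # amax recycles along rows (samples)
  e / rowSums(e)
}

# One dropout mask, inverted scaling; NULL means "no dropout".
.drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix((runif(nr * nc) < keep) / keep, nr, nc)
}

.mask <- function(x, m) if (is.null(m)) x else x * m

# Column-wise broadcast helpers (recycling along columns is much cheaper
# than sweep() in the training loop).
.add_cols <- function(x, v) x + rep(v, each = nrow(x))
.mul_cols <- function(x, v) x * rep(v, each = nrow(x))
.div_cols <- function(x, v) x / rep(v, each = nrow(x))
.sub_cols <- function(x, v) x - rep(v, each = nrow(x))

# Full forward pass over a batch. X is n x d (already scaled), E is d x m.
# bn gives running statistics (used when training = FALSE). Returns every
# intermediate needed by nn_backward.
nn_forward <- function(X, E, par, bn, training = FALSE, dropout_rate = 0,
                       masks = NULL) {
  if (any(!is.finite(X))) stop("non-finite values in the input batch", call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  p <- ncol(par$Wx); ha <- ncol(par$Wa1); hy <- ncol(par$Wy1)
  s <- as.vector(X)                       # (j, i) at (i-1)*n + j
  idx_feat <- rep(seq_len(d), each = n)
  idx_samp <- rep(seq_len(n), times = d)

  if (training && dropout_rate > 0 && is.null(masks)) {
    masks <- list(U = .drop_mask(n * d, p, dropout_rate),
                  V = .drop_mask(n * d, ha, dropout_rate),
                  r = .drop_mask(n, hy, dropout_rate))
  }

  A <- E %*% par$Wx                       # d x p
  C <- E %*% par$Wa1                      # d x ha
  U <- tanh(.add_cols(s * A[idx_feat, , drop = FALSE], par$bx))
  V <- tanh(.add_cols(s * C[idx_feat, , drop = FALSE], par$ba1))
  U_d <- .mask(U, masks$U)
  V_d <- .mask(V, masks$V)

  alpha <- matrix(as.vector(V_d %*% par$wa2) + par$ba2, n, d)
  beta <- .softmax_rows(alpha)
  bv <- as.vector(beta)

  xbar <- rowsum(bv * U_d, group = idx_samp, reorder = TRUE)
  dimnames(xbar) <- NULL

  z1 <- .add_cols(xbar %*% par$Wy1, par$by1)
  if (training) {
    mu <- colMeans(z1)
    v <- colMeans(z1^2) - mu^2
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  sdv <- sqrt(v + .bn_eps)
  xhat <- .div_cols(.sub_cols(z1, mu), sdv)
  z1n <- .add_cols(.mul_cols(xhat, par$gamma), par$delta)
  r <- pmax(z1n, 0)
  r_d <- .mask(r, masks$r)
  logit <- as.vector(r_d %*% par$wy2) + par$by2
  prob <- plogis(logit)

  list(prob = prob, logit = logit, beta = beta, alpha = alpha, xbar = xbar,
       s = s, idx_feat = idx_feat, idx_samp = idx_samp,
       U = U, V = V, U_d = U_d, V_d = V_d,
       z1n = z1n, xhat = xhat, sdv = sdv, r_d = r_d,
       batch_mu = mu, batch_var = v, masks = masks,
       training = training, n = n, d = d)
}

# Numerically stable mean binary log-loss; w are per-sample weights that
# average to 1 (all-ones by default).
nn_loss <- function(logit, y, w = NULL) {
  sp <- pmax(logit, 0) + log1p(exp(-abs(logit)))   # softplus(logit)
  l <- sp - y * logit
  if (!is.null(w)) l <- l * w
  mean(l)
}

# Gradients of nn_loss with respect to every parameter, reusing the forward
# cache. Valid for the mode (training / evaluation) the forward was run in.
nn_backward <- function(fw, E, par, y, w = NULL) {
  n <- fw$n
  g <- (fw$prob - y) / n
  if (!is.null(w)) g <- g * w

  dwy2 <- as.vector(crossprod(fw$r_d, g))
  dby2 <- sum(g)
  dr <- .mask(outer(g, par$wy2), fw$masks$r)
  dz1n <- dr * (fw$z1n > 0)

  dgamma <- colSums(dz1n * fw$xhat)
  ddelta <- colSums(dz1n)
  dxhat <- .mul_cols(dz1n, par$gamma)
  if (fw$training) {
    dz1 <- .sub_cols(n * dxhat, colSums(dxhat)) -
      .mul_cols(fw$xhat, colSums(dxhat * fw$xhat))
    dz1 <- .div_cols(dz1, n * fw$sdv)
  } else {
    dz1 <- .div_cols(dxhat, fw$sdv)
  }
  dWy1 <- crossprod(fw$xbar, dz1)
  dby1 <- colSums(dz1)
  dxbar <- dz1 %*% t(par$Wy1)

  dxbar_exp <- dxbar[fw$idx_samp, , drop = FALSE]
  bv <- as.vector(fw$beta)
  dU_d <- bv * dxbar_exp
  dbeta <- matrix(rowSums(fw$U_d * dxbar_exp), n, fw$d)
  dalpha <- fw$beta * (dbeta - rowSums(fw$beta * dbeta))
  dalpha_vec <- as.vector(dalpha)

  dwa2 <- as.vector(crossprod(fw$V_d, dalpha_vec))
  dba2 <- sum(dalpha_vec)
  dV <- .mask(outer(dalpha_vec, par$wa2), fw$masks$V)
  dQ <- dV * (1 - fw$V^2)
  Ga <- rowsum(dQ * fw$s, group = fw$idx_feat, reorder = TRUE)
  dWa1 <- crossprod(E, Ga)
  dba1 <- colSums(dQ)

  dU <- .mask(dU_d, fw$masks$U)
  dP <- dU * (1 - fw$U^2)
  Gx <- rowsum(dP * fw$s, group = fw$idx_feat, reorder = TRUE)
  dWx <- crossprod(E, Gx)
  dbx <- colSums(dP)

  list(Wx = dWx, bx = dbx, Wa1 = dWa1, ba1 = dba1, wa2 = dwa2, ba2 = dba2,
       Wy1 = dWy1, by1 = dby1, gamma = dgamma, delta = ddelta,
       wy2 = dwy2, by2 = dby2)
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0),
       t = 0L)
}

# Adam with decoupled weight decay on the weight matrices/vectors (biases
# and the batch-norm affine parameters are not decayed, the usual AdamW
# convention).
.decayed <- c("Wx", "Wa1", "wa2", "Wy1", "wy2")

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && nm %in% .decayed) {
      step <- step + lr * weight_decay * par[[nm]]
    }
    par[[nm]] <- par[[nm]] - step
  }
  list(par = par, state = state)
}
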
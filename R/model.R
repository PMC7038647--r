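#' Model configuration
#'
#' Architecture and optimisation hyperparameters for the attention
#' classifier. The defaults follow the regime m << d and p << m that makes
#' attention tractable when features vastly outnumber samples; none of them
#' is data-derived and all can be overridden.
#'
#' @param m Embedding dimension (default 64).
#' @param p Representation dimension (default 16; keep p <= m).
#' @param alpha_hidden Hidden width of the attention scorer f_alpha (default 32).
#' @param y_hidden Hidden width of the classifier f_y (default 8).
#' @param dropout_rate Dropout probability applied to f_x, f_alpha and f_y
#'   during training only (default 0.5).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size (default 16; must be >= 2 because the
#'   classifier head uses batch normalisation). Small batches give the
#'   attention scorer enough gradient steps to concentrate weight on
#'   informative features despite the softmax dilution over d features.
#' @param seed Integer seed controlling embedding construction, parameter
#'   initialisation, batching and dropout; the whole fit is reproducible
#'   given the seed.
#' @param scale_features Input transform applied before embedding, learned
#'   on the training set: `"pooled"` (default; log1p, centre each feature,
#'   divide by the pooled feature standard deviation), `"zscore"` (log1p
#'   and per-feature standardisation), or `"none"`. Logical values are
#'   accepted (`TRUE` = `"pooled"`). Normalised counts span orders of
#'   magnitude and would saturate the tanh units untransformed; the pooled
#'   variant additionally preserves between-feature differences in spread,
#'   which are informative for the attention scorer.
#' @param validation_fraction Fraction of training samples held out
#'   (stratified) for per-epoch loss monitoring (default 0.1; 0 disables).
#' @param early_stopping Restore the parameters with the best validation
#'   loss when it stops improving (default `FALSE`; monitoring only).
#' @param patience Epochs without validation improvement tolerated when
#'   `early_stopping = TRUE` (default 10).
#' @param class_weights Weight the log-loss by inverse class frequency
#'   (default `FALSE`).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   weight matrices, not to biases or batch-norm parameters (default 0:
#'   dropout is the model's regulariser). Values around 1e-3 smooth the
#'   attention scorer, which strengthens low-variance structure in the
#'   importance matrix (e.g. within-class heterogeneity axes) at the cost
#'   of a less sparse discriminative factor.
#' @return A list of class `"triage_config"`.
#' @export
triage_config <- function(m = 64L, p = 16L, alpha_hidden = 32L, y_hidden = 8L,
                          dropout_rate = 0.5, learning_rate = 0.01,
                          epochs = 500L, batch_size = 16L, seed = 1L,
                          scale_features = "pooled", validation_fraction = 0.1,
                          early_stopping = FALSE, patience = 10L,
                          class_weights = FALSE, weight_decay = 0) {
  stopifnot(m >= 1, p >= 1, alpha_hidden >= 1, y_hidden >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, epochs >= 1, batch_size >= 2,
            validation_fraction >= 0, validation_fraction < 1,
            weight_decay >= 0)
  structure(list(m = as.integer(m), p = as.integer(p),
                 alpha_hidden = as.integer(alpha_hidden),
                 y_hidden = as.integer(y_hidden),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 scale_features = .scale_method(scale_features),
                 validation_fraction = validation_fraction,
                 early_stopping = early_stopping, patience = as.integer(patience),
                 class_weights = class_weights, weight_decay = weight_decay),
            class = "triage_config")
}

# Apply (or learn) the model's input transform, with training-set
# statistics: log1p then per-feature centring, then either per-feature unit
# variance ("zscore") or division by the pooled (root-mean-square) feature
# standard deviation ("pooled", the default) — the latter keeps the inputs
# on a tanh-friendly scale while preserving between-feature differences in
# spread, which carry signal for the attention scorer. sd == 0 columns fall
# back to 1.
.scale_learn <- function(x, method) {
  method <- .scale_method(method)
  if (method == "none") {
    return(list(enabled = FALSE, center = NULL, scale = NULL))
  }
  lx <- log1p(x)
  ctr <- colMeans(lx)
  scl <- apply(lx, 2L, sd)
  if (method == "pooled") scl[] <- sqrt(mean(scl^2))
  scl[scl == 0] <- 1
  list(enabled = TRUE, center = ctr, scale = scl)
}

.scale_method <- function(method) {
  if (is.logical(method)) method <- if (method) "pooled" else "none"
  match.arg(method, c("pooled", "zscore", "none"))
}

.scale_apply <- function(x, scaling) {
  if (!scaling$enabled) return(x)
  sweep(sweep(log1p(x), 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

#' Fit the attention classifier
#'
#' Trains the embedding / self-attention / representation / classifier stack
#' end-to-end by minimising the binary log-loss with Adam. Features are
#' embedded against a fixed random matrix; each feature's attention score is
#' computed from its own embedded value with shared weights and softmax-
#' normalised across features, so every sample gets a probability together
#' with a per-feature importance vector beta that sums to one.
#'
#' @param x Samples x features matrix of non-negative values with dimnames
#'   (typically normalised counts or annotation-level sums).
#' @param y Binary labels (0/1), one per sample; 1 denotes the positive
#'   class (e.g. luminal A). Both classes must be present with at least two
#'   samples each.
#' @param config A [triage_config()].
#' @return An object of class `"triage_model"`: fixed embedding, trained
#'   parameters, batch-norm running statistics, input-scaling statistics,
#'   the feature universe, and a per-epoch `training_log`.
#' @export
triage_fit <- function(x, y, config = triage_config()) {
  validate_expression(x, "training matrix")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("labels do not align with samples", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (min(table(y)) < 2 || length(unique(y)) < 2) {
    stop("need at least two samples in each of the two classes", call. = FALSE)
  }
  cfg <- config
  d <- ncol(x)
  if (cfg$m >= d) {
    warning("embedding dimension m = ", cfg$m, " is not smaller than d = ", d,
            "; the model is intended for m << d", call. = FALSE)
  }

  scaling <- .scale_learn(x, cfg$scale_features)
  Xs <- .scale_apply(x, scaling)
  E <- build_embedding(d, cfg$m, seed = cfg$seed)

  withr::local_seed(cfg$seed + 1L)
  par <- nn_init_params(cfg$m, cfg$p, cfg$alpha_hidden, cfg$y_hidden)
  bn <- list(mean = numeric(cfg$y_hidden), var = rep(1, cfg$y_hidden))
  state <- adam_init(par)

  # optional stratified validation split for loss monitoring
  n <- nrow(Xs)
  val_idx <- integer(0)
  if (cfg$validation_fraction > 0) {
    for (cl in c(0, 1)) {
      cls <- which(y == cl)
      n_val <- floor(length(cls) * cfg$validation_fraction)
      if (n_val >= 1 && length(cls) - n_val >= 2) {
        val_idx <- c(val_idx, sample(cls, n_val))
      }
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- Xs[val_idx, , drop = FALSE]; yval <- y[val_idx]

  w_tr <- NULL
  if (cfg$class_weights) {
    freq <- table(factor(ytr, levels = c(0, 1))) / length(ytr)
    w_tr <- as.numeric(1 / (2 * freq[as.character(ytr)]))
  }

  log_rows <- vector("list", cfg$epochs)
  best <- list(val = Inf, par = par, bn = bn, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(ytr))
    starts <- seq(1L, length(ord), by = cfg$batch_size)
    epoch_loss <- 0; epoch_n <- 0L
    for (st in starts) {
      b <- ord[st:min(st + cfg$batch_size - 1L, length(ord))]
      if (length(b) < 2L) next  # batch norm needs >= 2 samples
      fw <- nn_forward(Xtr[b, , drop = FALSE], E, par, bn, training = TRUE,
                       dropout_rate = cfg$dropout_rate)
      wb <- if (is.null(w_tr)) NULL else w_tr[b]
      loss <- nn_loss(fw$logit, ytr[b], wb)
      if (!is.finite(loss)) {
        stop("training loss became non-finite at epoch ", epoch, call. = FALSE)
      }
      grads <- nn_backward(fw, E, par, ytr[b], wb)
      upd <- adam_step(par, grads, state, cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
      par <- upd$par; state <- upd$state
      nb <- length(b)
      bn$mean <- (1 - .bn_momentum) * bn$mean + .bn_momentum * fw$batch_mu
      bn$var <- (1 - .bn_momentum) * bn$var +
        .bn_momentum * fw$batch_var * nb / (nb - 1)
      epoch_loss <- epoch_loss + loss * nb
      epoch_n <- epoch_n + nb
    }
    mean_loss <- epoch_loss / epoch_n
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      fv <- nn_forward(Xval, E, par, bn, training = FALSE)
      val_loss <- nn_loss(fv$logit, yval)
      if (val_loss < best$val - 1e-8) {
        best <- list(val = val_loss, par = par, bn = bn, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = mean_loss,
                                    val_loss = val_loss)
    if (cfg$early_stopping && length(val_idx) > 0 && stall >= cfg$patience) {
      log_rows <- log_rows[seq_len(epoch)]
      break
    }
  }
  if (cfg$early_stopping && length(val_idx) > 0 && best$epoch > 0L) {
    par <- best$par; bn <- best$bn
  }

  structure(list(par = par, bn = bn, embedding = E, config = cfg,
                 scaling = scaling, features = colnames(x),
                 training_log = do.call(rbind, log_rows)),
            class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cfg <- x$config
  cat("Attention classifier over", length(x$features), "features\n")
  cat("  m =", cfg$m, " p =", cfg$p,
      " hidden(alpha) =", cfg$alpha_hidden, " hidden(y) =", cfg$y_hidden, "\n")
  tl <- x$training_log
  cat("  trained", nrow(tl), "epochs; final loss",
      format(tl$loss[nrow(tl)], digits = 4), "\n")
  invisible(x)
}

# ---- per-sample stage functions -------------------------------------------
# These spell out the model definition one sample at a time; the batched
# trainer above is tested against them.

#' Attention scores for one embedded sample
#'
#' Applies the attention scorer f_alpha independently to each feature's
#' embedded vector (shared weights) and softmax-normalises across features.
#' The softmax subtracts the row maximum, so arbitrary score magnitudes are
#' safe.
#'
#' @param embedded d x m matrix from [embed_sample()] (evaluation mode; no
#'   dropout).
#' @param model A fitted `triage_model`.
#' @return List with `alpha` (raw scores) and `beta` (importance weights,
#'   positive, summing to 1).
#' @export
attention_scores <- function(embedded, model) {
  if (any(!is.finite(embedded))) stop("non-finite embedded values", call. = FALSE)
  par <- model$par
  H <- tanh(sweep(embedded %*% par$Wa1, 2L, par$ba1, "+"))
  alpha <- as.vector(H %*% par$wa2) + par$ba2
  a <- alpha - max(alpha)
  beta <- exp(a) / sum(exp(a))
  list(alpha = alpha, beta = beta)
}

#' Attention-weighted sample representation
#'
#' xbar = sum_i beta_i f_x(embedded_i): a convex combination of the tanh
#' feature representations, so every coordinate lies in (-1, 1).
#'
#' @param embedded d x m embedded sample.
#' @param beta Importance weights summing to 1.
#' @param model A fitted `triage_model`.
#' @return Numeric vector of length p.
#' @export
represent_sample <- function(embedded, beta, model) {
  par <- model$par
  if (length(beta) != nrow(embedded)) stop("beta does not match features", call. = FALSE)
  Fx <- tanh(sweep(embedded %*% par$Wx, 2L, par$bx, "+"))
  as.vector(crossprod(Fx, beta))
}

#' Class probability from a sample representation
#'
#' Classifier head in evaluation mode: linear layer, batch normalisation
#' with the stored running statistics, ReLU, then a sigmoid output.
#'
#' @param x_bar Length-p representation vector.
#' @param model A fitted `triage_model`.
#' @return Probability of the positive class, strictly in (0, 1).
#' @export
predict_proba <- function(x_bar, model) {
  if (any(!is.finite(x_bar))) stop("non-finite representation", call. = FALSE)
  par <- model$par; bn <- model$bn
  z1 <- as.vector(crossprod(par$Wy1, x_bar)) + par$by1
  xhat <- (z1 - bn$mean) / sqrt(bn$var + .bn_eps)
  r <- pmax(par$gamma * xhat + par$delta, 0)
  plogis(sum(r * par$wy2) + par$by2)
}

#' Forward pass for a single sample
#'
#' Composes embedding, attention, representation and classification in
#' evaluation mode, returning both the class probability and the importance
#' weights.
#'
#' @param model A fitted `triage_model`.
#' @param x Length-d vector on the original feature scale (the model's input
#'   transform is applied internally).
#' @return List with `prob` and `beta`.
#' @export
triage_forward <- function(model, x) {
  if (length(x) != length(model$features)) {
    stop("sample length does not match the model's feature universe", call. = FALSE)
  }
  xs <- as.vector(.scale_apply(matrix(x, 1L), model$scaling))
  emb <- embed_sample(xs, model$embedding)
  att <- attention_scores(emb, model)
  xbar <- represent_sample(emb, att$beta, model)
  list(prob = predict_proba(xbar, model), beta = att$beta)
}

# Align a new matrix to the model's feature universe, with a precise error.
.align_features <- function(model, x) {
  validate_expression(x, "new data")
  miss <- setdiff(model$features, colnames(x))
  extra <- setdiff(colnames(x), model$features)
  if (length(miss) || length(extra)) {
    stop("feature mismatch with the fitted model; missing: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...", "; unexpected: ",
         paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ...", call. = FALSE)
  }
  x[, model$features, drop = FALSE]
}

#' Predict from a fitted attention model
#'
#' @param object A `triage_model`.
#' @param newdata Samples x features matrix on the original scale; features
#'   must match the training universe (any column order).
#' @param type `"prob"` for class-1 probabilities, `"beta"` for the
#'   importance matrix, `"both"` for a list with both.
#' @param ... Unused.
#' @return Per `type`; evaluation mode throughout (no dropout, frozen batch
#'   normalisation), so each sample's output is independent of its batch.
#' @export
predict.triage_model <- function(object, newdata, type = c("prob", "beta", "both"),
                                 ...) {
  type <- match.arg(type)
  x <- .align_features(object, newdata)
  Xs <- .scale_apply(x, object$scaling)
  fw <- nn_forward(Xs, object$embedding, object$par, object$bn, training = FALSE)
  prob <- setNames(fw$prob, rownames(x))
  beta <- fw$beta
  dimnames(beta) <- dimnames(x)
  switch(type, prob = prob, beta = beta, both = list(prob = prob, beta = beta))
}

#' Per-sample importance matrix on a held-out set
#'
#' Stacks the attention weight vectors beta_j of the given (typically
#' test-set) samples into the importance matrix B. Rows are samples, columns
#' features; every row is positive and sums to one.
#'
#' @param model A fitted `triage_model`.
#' @param test Samples x features matrix on the original scale.
#' @return Matrix of class `"importance_matrix"` with sample and feature
#'   dimnames.
#' @export
score_importance <- function(model, test) {
  B <- predict(model, test, type = "beta")
  structure(B, class = c("importance_matrix", class(B)))
}

#' Save / load a fitted model
#'
#' The archive is a single self-describing RDS list (configuration,
#' embedding seed and matrix, weights, batch-norm statistics, scaling);
#' loading reproduces forward outputs bit-for-bit.
#'
#' @param model A `triage_model`.
#' @param path File path.
#' @return `save_triage_model` the path, invisibly; `load_triage_model` the
#'   model.
#' @export
save_triage_model <- function(model, path) {
  stopifnot(inherits(model, "triage_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_triage_model
#' @export
load_triage_model <- function(path) {
  structure(readRDS(path), class = "triage_model")
}

#' Finite-difference check of the analytic gradients
#'
#' Builds a small random instance, computes the analytic gradients of the
#' mean log-loss (training mode, dropout disabled so the loss is
#' deterministic) and compares every parameter against central finite
#' differences.
#'
#' @param n,d Samples and features of the random instance.
#' @param config Architecture to check (dropout is forced to 0).
#' @param seed Seed for the instance.
#' @param h Finite-difference step.
#' @return Maximum relative error over all parameters, where the relative
#'   error uses `max(|analytic| + |numeric|, 1e-6)` as denominator.
#' @export
triage_gradient_check <- function(n = 8L, d = 20L,
                                  config = triage_config(m = 4L, p = 2L,
                                                         alpha_hidden = 3L,
                                                         y_hidden = 3L),
                                  seed = 1L, h = 1e-5) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(0, 1), length.out = n)
  E <- build_embedding(d, config$m, seed = seed)
  par <- nn_init_params(config$m, config$p, config$alpha_hidden, config$y_hidden)
  bn <- list(mean = numeric(config$y_hidden), var = rep(1, config$y_hidden))

  loss_at <- function(p) {
    fw <- nn_forward(X, E, p, bn, training = TRUE, dropout_rate = 0)
    nn_loss(fw$logit, y)
  }
  fw <- nn_forward(X, E, par, bn, training = TRUE, dropout_rate = 0)
  an <- nn_backward(fw, E, par, y)

  max_rel <- 0
  for (nm in names(par)) {
    for (k in seq_along(par[[nm]])) {
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      a <- an[[nm]][k]
      rel <- abs(a - num) / max(abs(a) + abs(num), 1e-6)
      if (rel > max_rel) max_rel <- rel
    }
  }
  max_rel
}
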
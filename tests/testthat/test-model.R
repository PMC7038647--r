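test_that("embedding construction is seeded, shaped, and moment-correct", {
  expect_identical(build_embedding(5, 3, seed = 9), build_embedding(5, 3, seed = 9))
  expect_equal(dim(build_embedding(5, 3, seed = 1)), c(5L, 3L))
  expect_error(build_embedding(0, 3), "positive")

  # N(0, 1/m) moments on a large draw, within 3 standard errors
  m <- 8L
  E <- build_embedding(10000L, m, seed = 2)
  n <- length(E)
  sd_target <- 1 / sqrt(m)
  expect_lt(abs(mean(E) - 0), 3 * sd_target / sqrt(n))
  se_var <- sd_target^2 * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.vector(E)) - sd_target^2), 3 * se_var)
})

test_that("embed_sample is the multiplicative interaction x_ji * e_i", {
  E <- matrix(c(0.5, -1, 2, 0.25), 2, 2, byrow = TRUE)
  emb <- embed_sample(c(2, 3), E)
  expect_equal(emb[1, ], c(1.0, -2.0))
  expect_equal(emb[2, ], c(6, 0.75))

  x <- c(0, 4)
  expect_equal(embed_sample(x, E)[1, ], c(0, 0))     # zero maps to zero row
  expect_equal(embed_sample(2 * x, E), 2 * embed_sample(x, E))  # linearity
  expect_error(embed_sample(c(1, 2, 3), E), "match")
})

test_that("attention weights are a softmax over per-feature scores", {
  # analytic softmax: alpha = (ln 1, ln 3) -> beta = (0.25, 0.75)
  expect_equal(as.vector(exprattn:::.softmax_rows(matrix(log(c(1, 3)), 1))),
               c(0.25, 0.75))

  model <- make_toy_model(d = 1L)
  att1 <- attention_scores(matrix(rnorm(4), 1, 4), model)
  expect_equal(att1$beta, 1)                         # singleton softmax

  model6 <- make_toy_model(d = 6L)
  emb_same <- matrix(rep(rnorm(4), each = 6), 6, 4)  # identical rows
  expect_equal(attention_scores(emb_same, model6)$beta, rep(1 / 6, 6))

  withr::local_seed(1)
  emb <- matrix(rnorm(24), 6, 4)
  att <- attention_scores(emb, model6)
  expect_equal(sum(att$beta), 1, tolerance = 1e-12)
  expect_true(all(att$beta > 0))
  expect_error(attention_scores(emb * NA, model6), "non-finite")
})

test_that("represent_sample is the beta-weighted sum of tanh representations", {
  model <- make_toy_model(d = 5L, m = 4L, p = 3L)
  withr::local_seed(2)
  emb <- matrix(rnorm(20), 5, 4)

  # degenerate one-hot mixture picks out a single feature representation
  beta1 <- c(0, 0, 1, 0, 0)
  expect_equal(represent_sample(emb, beta1, model),
               as.vector(tanh(emb[3, ] %*% model$par$Wx + model$par$bx)))

  # brute-force loop oracle
  beta <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  oracle <- numeric(3)
  for (i in 1:5) {
    oracle <- oracle + beta[i] *
      tanh(as.vector(emb[i, ] %*% model$par$Wx) + model$par$bx)
  }
  expect_equal(represent_sample(emb, beta, model), oracle, tolerance = 1e-6)

  # convex combination of tanh outputs stays inside (-1, 1)
  expect_true(all(abs(represent_sample(emb, beta, model)) < 1))
  expect_error(represent_sample(emb, c(0.5, 0.5), model), "match")
})

test_that("predict_proba is a sigmoid over the classifier head", {
  model <- make_toy_model()
  withr::local_seed(3)
  xbar <- rnorm(3, sd = 0.5)
  pr <- predict_proba(xbar, model)
  expect_gt(pr, 0); expect_lt(pr, 1)

  # zeroed output layer gives sigmoid(0) = 0.5
  m0 <- model
  m0$par$wy2[] <- 0; m0$par$by2 <- 0
  expect_equal(predict_proba(xbar, m0), 0.5)

  # closed-form check from the penultimate layer
  par <- model$par; bn <- model$bn
  z1 <- as.vector(crossprod(par$Wy1, xbar)) + par$by1
  r <- pmax(par$gamma * (z1 - bn$mean) / sqrt(bn$var + 1e-5) + par$delta, 0)
  L <- sum(r * par$wy2) + par$by2
  expect_equal(predict_proba(xbar, model), 1 / (1 + exp(-L)), tolerance = 1e-6)
  expect_error(predict_proba(c(NA, 1, 2), model), "non-finite")
})

test_that("the batched forward equals the composed per-sample stages", {
  model <- make_toy_model(d = 8L, m = 4L, p = 3L)
  withr::local_seed(4)
  X <- matrix(rexp(5 * 8), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:8)))
  out <- predict(model, X, type = "both")
  for (j in 1:5) {
    one <- triage_forward(model, X[j, ])
    expect_equal(unname(out$prob[j]), one$prob, tolerance = 1e-6)
    expect_equal(unname(out$beta[j, ]), one$beta, tolerance = 1e-6)
  }
})

test_that("feature permutation permutes beta and leaves probabilities alone", {
  model <- make_toy_model(d = 7L, m = 4L)
  withr::local_seed(5)
  X <- matrix(rexp(3 * 7), 3, 7,
              dimnames = list(paste0("s", 1:3), paste0("g", 1:7)))
  perm <- sample(7)
  model_p <- model
  model_p$embedding <- model$embedding[perm, ]
  model_p$features <- model$features[perm]
  out <- predict(model, X, type = "both")
  out_p <- predict(model_p, X[, perm], type = "both")
  expect_equal(out_p$prob, out$prob, tolerance = 1e-6)
  expect_equal(out_p$beta, out$beta[, perm], tolerance = 1e-6)
})

test_that("zero expression yields a sample-independent attention score", {
  model <- make_toy_model(d = 5L, scale_features = FALSE)
  X <- rbind(c(0, 1, 2, 0, 3),
             c(0, 4, 1, 0, 9))
  a1 <- attention_scores(embed_sample(X[1, ], model$embedding), model)$alpha
  a2 <- attention_scores(embed_sample(X[2, ], model$embedding), model)$alpha
  expect_equal(a1[c(1, 4)], a2[c(1, 4)])  # f_alpha(0), shared constant
  # and it is exactly f_alpha at the zero vector
  a0 <- attention_scores(matrix(0, 5, 4), model)$alpha
  expect_equal(a1[1], a0[1])
})

test_that("evaluation outputs are independent of batch composition", {
  model <- make_toy_model(d = 6L)
  withr::local_seed(6)
  X <- matrix(rexp(8 * 6), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  full <- predict(model, X, type = "both")
  one <- predict(model, X[3, , drop = FALSE], type = "both")
  expect_equal(one$prob, full$prob[3], tolerance = 1e-6)
  expect_equal(one$beta[1, ], full$beta[3, ], tolerance = 1e-6)
})

test_that("training is reproducible and reduces the loss on separable data", {
  coh <- quick_cohort()
  feats <- preprocess_counts(coh$counts)$features
  cfg <- quick_config(seed = 2, epochs = 10L)
  m1 <- triage_fit(feats, coh$labels, cfg)
  m2 <- triage_fit(feats, coh$labels, cfg)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$training_log, m2$training_log)

  # loss trend on separable data at this fixed seed
  expect_true(all(diff(m1$training_log$loss[1:5]) <= 0))
  expect_lt(m1$training_log$loss[10], m1$training_log$loss[1])
})

test_that("degenerate labels are rejected", {
  coh <- quick_cohort()
  feats <- preprocess_counts(coh$counts)$features
  expect_error(triage_fit(feats, rep(1, nrow(feats)), quick_config()),
               "two samples in each")
  expect_error(triage_fit(feats, coh$labels[-1], quick_config()), "align")
  expect_error(triage_fit(feats, replace(coh$labels, 1, 2), quick_config()),
               "0/1")
})

test_that("flipping the labels flips the decision function", {
  coh <- quick_cohort(seed = 8)
  feats <- preprocess_counts(coh$counts)$features
  cfg <- quick_config(seed = 3, epochs = 20L)
  m_a <- triage_fit(feats, coh$labels, cfg)
  m_b <- triage_fit(feats, 1 - coh$labels, cfg)
  p_a <- predict(m_a, feats, type = "prob")
  p_b <- predict(m_b, feats, type = "prob")
  auc <- function(y, p) {
    r <- rank(p); n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  expect_gt(auc(coh$labels, p_a), 0.95)
  expect_lt(abs(auc(coh$labels, p_a) - auc(1 - coh$labels, p_b)), 0.05)
})

test_that("score_importance returns a stochastic matrix on the test set", {
  coh <- quick_cohort(seed = 9)
  feats <- preprocess_counts(coh$counts)$features
  split <- split_cohort(rownames(feats), coh$labels, seed = 4)
  model <- triage_fit(feats[split$train, ], coh$labels[split$train],
                      quick_config(seed = 5))
  B <- score_importance(model, feats[split$test, ])
  expect_equal(dim(B), c(length(split$test), ncol(feats)))
  expect_equal(unname(rowSums(B)), rep(1, nrow(B)), tolerance = 1e-6)
  expect_true(all(B > 0))
  expect_identical(rownames(B), split$test)

  # feature mismatch is reported precisely
  bad <- feats[split$test, ]
  colnames(bad)[1] <- "unknown_feature"
  expect_error(score_importance(model, bad), "feature mismatch")
})

test_that("a saved model reproduces its forward outputs exactly", {
  model <- make_toy_model(d = 6L)
  withr::local_seed(10)
  X <- matrix(rexp(4 * 6), 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:6)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_triage_model(model, f)
  m2 <- load_triage_model(f)
  expect_identical(predict(m2, X, type = "both"), predict(model, X, type = "both"))
})
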
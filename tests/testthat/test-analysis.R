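# Importance-matrix rows for tests: block-structured stochastic matrices
# with optional noise.
block_importance <- function(n_per_class = 10L, d = 10L, block = 1:5,
                             noise = 0, seed = 1L) {
  withr::local_seed(seed)
  n <- 2L * n_per_class
  B <- matrix(noise * runif(n * d), n, d)
  labels <- rep(c(1, 0), each = n_per_class)
  B[labels == 1, block] <- B[labels == 1, block] + 1
  B[labels == 0, setdiff(seq_len(d), block)] <-
    B[labels == 0, setdiff(seq_len(d), block)] + 1
  B <- B / rowSums(B)
  dimnames(B) <- list(sprintf("s%02d", seq_len(n)), sprintf("f%02d", seq_len(d)))
  list(B = B, labels = labels)
}

test_that("NMF recovers a planted class-aligned block", {
  bi <- block_importance(noise = 0.05)
  fit <- nmf_factorise(bi$B, bi$labels, k = 2, seed = 1)
  top5 <- names(sort(fit$contributions[fit$discriminative_factor, ],
                     decreasing = TRUE))[1:5]
  expect_setequal(top5, sprintf("f%02d", 1:5))
  # contributions are per-factor normalised
  expect_equal(unname(rowSums(fit$contributions)), rep(1, 2), tolerance = 1e-8)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("NMF objective is monotone and capacity increases with rank", {
  bi <- block_importance(noise = 0.2, seed = 3)
  fit2 <- nmf_factorise(bi$B, bi$labels, k = 2, seed = 1)
  expect_true(all(diff(fit2$objective) <= 1e-8))
  k_full <- min(dim(bi$B))
  fit_full <- nmf_factorise(bi$B, bi$labels, k = k_full, seed = 1)
  expect_lte(fit_full$recon_error, fit2$recon_error)

  # seeded determinism of the random initialisation
  fa <- nmf_factorise(bi$B, bi$labels, k = 3, seed = 5, init = "random")
  fb <- nmf_factorise(bi$B, bi$labels, k = 3, seed = 5, init = "random")
  expect_identical(fa$W, fb$W)
  expect_identical(fa$H, fb$H)

  expect_error(nmf_factorise(-bi$B, bi$labels, k = 2), "negative")
  expect_error(nmf_factorise(bi$B, bi$labels, k = 100), "min\\(n, d\\)")
})

test_that("PCA ordination satisfies the SVD identities", {
  withr::local_seed(4)
  # exact 1-D structure
  t_par <- seq(0, 1, length.out = 8)
  dir <- c(1, 2, -1, 0.5)
  B1 <- outer(t_par, dir) + matrix(rep(c(3, 1, 2, 0), each = 8), 8, 4)
  rownames(B1) <- paste0("s", 1:8); colnames(B1) <- paste0("f", 1:4)
  ord1 <- pca_ordinate(B1, r = 4)
  expect_equal(ord1$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(sum(ord1$explained_variance_ratio), 1, tolerance = 1e-12)

  B <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  ord <- pca_ordinate(B, r = 4)
  # loadings orthonormal
  expect_equal(crossprod(ord$loadings), diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)
  # explained variance non-increasing, within [0, 1]
  expect_true(all(diff(ord$explained_variance_ratio) <= 1e-12))
  expect_true(all(ord$explained_variance_ratio >= 0 &
                  ord$explained_variance_ratio <= 1))
  centred <- sweep(B, 2, ord$center)
  # projection identity and full reconstruction
  expect_equal(ord$scores, centred %*% ord$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ord$scores %*% t(ord$loadings), centred, tolerance = 1e-8,
               ignore_attr = TRUE)

  # sample permutation equivariance up to axis sign
  perm <- c(3, 1, 6, 2, 5, 4)
  ord_p <- pca_ordinate(B[perm, ], r = 4)
  for (k in 1:4) {
    s <- sign(sum(ord_p$loadings[, k] * ord$loadings[, k]))
    expect_equal(ord_p$scores[, k], s * ord$scores[perm, k], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(pca_ordinate(B, r = 10), "exceeds")
})

test_that("stage models recover saturated and graded effects", {
  withr::local_seed(5)
  n <- 60
  stage <- sample(1:4, n, TRUE)
  ids <- sprintf("s%02d", 1:n)
  clin <- data.frame(sample_id = ids, T = paste0("T", stage),
                     N = "N0", M = "M0")

  # indicator outcome: T4 coefficient exactly 1, other T levels 0
  scores <- matrix(as.numeric(stage == 4), ncol = 1,
                   dimnames = list(ids, "PC1"))
  suppressWarnings(a <- stage_association(scores, clin))
  expect_equal(a$estimate[a$level == "T4"], 1, tolerance = 1e-12)
  expect_equal(a$estimate[a$level != "T4"], rep(0, 2), tolerance = 1e-12)

  # graded outcome: monotone increasing T coefficients
  withr::local_seed(6)
  n2 <- 100
  st2 <- sample(1:4, n2, TRUE)
  ids2 <- sprintf("q%03d", 1:n2)
  clin2 <- data.frame(sample_id = ids2, T = paste0("T", st2),
                      N = sample(c("N0", "N1"), n2, TRUE), M = "M0")
  sc2 <- matrix(st2 + rnorm(n2, 0, 0.1), ncol = 1, dimnames = list(ids2, "PC1"))
  suppressWarnings(a2 <- stage_association(sc2, clin2))
  tc <- a2$estimate[a2$factor == "T"][order(a2$level[a2$factor == "T"])]
  expect_true(all(diff(tc) > 0))
  expect_true(all(a2$p_value[a2$factor == "T"] < 1e-6))
})

test_that("a single binary factor reduces to the two-sample t-test", {
  withr::local_seed(7)
  n <- 40
  grp <- rep(c("T1", "T2"), each = n / 2)
  ids <- sprintf("s%02d", 1:n)
  y <- rnorm(n) + (grp == "T2") * 0.8
  clin <- data.frame(sample_id = ids, T = grp, N = "N0", M = "M0")
  scores <- matrix(y, ncol = 1, dimnames = list(ids, "PC1"))
  expect_warning(a <- stage_association(scores, clin), "constant")
  tt <- t.test(y[grp == "T2"], y[grp == "T1"], var.equal = TRUE)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(a$estimate, unname(diff(tt$estimate)) * -1, tolerance = 1e-9)

  clin_const <- data.frame(sample_id = ids, T = "T1", N = "N0", M = "M0")
  expect_error(suppressWarnings(stage_association(scores, clin_const)),
               "constant")
})

test_that("subsetting by class restricts the stage model", {
  withr::local_seed(8)
  n <- 80
  ids <- sprintf("s%02d", 1:n)
  labels <- setNames(rep(c(1, 0), n / 2), ids)
  stage <- sample(1:3, n, TRUE)
  # signal only within class 1
  y <- ifelse(labels == 1, stage, 0) + rnorm(n, 0, 0.2)
  clin <- data.frame(sample_id = ids, T = paste0("T", stage), N = "N0", M = "M0")
  scores <- matrix(y, ncol = 1, dimnames = list(ids, "PC1"))
  suppressWarnings({
    a_sub <- stage_association(scores, clin, labels = labels, subset_class = 1)
  })
  expect_true(all(a_sub$p_value < 1e-6))
  expect_identical(attr(a_sub, "subset"), 1)
})

test_that("baselines separate separable data and not permuted labels", {
  withr::local_seed(9)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = rnorm(n, y * 6), b = rnorm(n, -y * 6))
  rownames(x) <- sprintf("s%03d", 1:n)
  bl <- run_baselines(x[1:60, ], y[1:60], x[61:n, ], y[61:n],
                      seed = 1, scale_features = FALSE)
  expect_equal(bl$f1, c(1, 1))

  # permuted labels: no better than chance-level F1
  withr::local_seed(10)
  n2 <- 500
  x2 <- matrix(rnorm(n2 * 20), n2, 20, dimnames = list(sprintf("r%03d", 1:n2), NULL))
  y2 <- sample(rep(c(0, 1), each = n2 / 2))
  tr <- 1:350; te <- 351:n2
  bl2 <- run_baselines(x2[tr, ], y2[tr], x2[te, ], y2[te], seed = 2,
                       scale_features = FALSE)
  expect_true(all(bl2$f1 <= 0.72))

  # memorising settings: in-sample F1 is at least the held-out F1
  bl_in <- run_baselines(x2[tr, ], y2[tr], x2[tr, ], y2[tr], seed = 2,
                         scale_features = FALSE, cost = 100)
  expect_true(all(bl_in$f1 >= bl2$f1 - 1e-9))

  expect_error(run_baselines(x2[tr, ], rep(1, 350), x2[te, ], y2[te]),
               "degenerate")
})

test_that("group mean differences follow the Welch test and sign convention", {
  withr::local_seed(11)
  n <- 100
  labels <- rep(c(0, 1), each = n / 2)
  x <- cbind(flat = rep(c(1, 2), n / 2),
             up0 = rnorm(n, ifelse(labels == 0, 5, 0)),
             const = rep(3, n))
  rownames(x) <- sprintf("s%03d", 1:n)
  # identical distribution in both classes by construction
  res <- group_mean_difference(x, labels)
  flat <- res[res$feature == "flat", ]
  expect_equal(flat$mean_diff, 0)

  up0 <- res[res$feature == "up0", ]
  expect_lt(up0$p_value, 1e-10)
  expect_gt(up0$mean_diff, 0)                    # higher in class 0
  expect_identical(up0$direction, "up_in_class0")

  cst <- res[res$feature == "const", ]
  expect_equal(cst$p_value, 1)                   # degenerate equal case
  expect_equal(cst$mean_diff, 0)

  expect_error(group_mean_difference(x, labels, "absent"), "not found")
  expect_error(group_mean_difference(x, rep(1, n)), "both classes")
})

test_that("plot helpers return ggplot objects", {
  bi <- block_importance(noise = 0.1, seed = 12)
  fit <- nmf_factorise(bi$B, bi$labels, k = 2, seed = 1)
  ord <- pca_ordinate(bi$B, r = 2)
  expect_s3_class(plot_factor_contributions(fit), "ggplot")
  expect_s3_class(plot_factor_scores(fit, bi$labels), "ggplot")
  expect_s3_class(plot_biplot(ord, bi$labels), "ggplot")
})
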
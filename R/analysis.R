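# Post-hoc interpretation of the importance matrix B: NMF with selection of
# the factor that best separates the two classes, PCA ordination, linear
# models of ordination axes against clinical T/N/M stage, plus the baseline
# classifiers used for benchmarking and simple per-feature tests.

.check_importance <- function(B) {
  if (!is.matrix(B) || !is.numeric(B)) stop("B must be a numeric matrix", call. = FALSE)
  if (any(B < 0)) stop("importance matrix has negative entries", call. = FALSE)
  rs <- rowSums(B)
  if (any(abs(rs - 1) > 1e-4)) {
    warning("importance rows do not sum to 1 (max deviation ",
            format(max(abs(rs - 1)), digits = 3), ")", call. = FALSE)
  }
  invisible(B)
}

# Standardised Wilcoxon rank-sum statistic of v between the two classes
# (normal approximation, no continuity correction). Large |z| = strong
# separation.
.ranksum_z <- function(v, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(v)
  U <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  (U - n1 * n0 / 2) / sqrt(n1 * n0 * (n1 + n0 + 1) / 12)
}

# Non-negative double-SVD initialisation with average fill (zeros replaced by
# the matrix mean) so multiplicative updates are not trapped at exact zeros.
.nndsvda <- function(B, k) {
  sv <- svd(B, nu = k, nv = k)
  n <- nrow(B); d <- ncol(B)
  W <- matrix(0, n, k); H <- matrix(0, k, d)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn && nup * nvp > 0) {
        sig <- sqrt(sv$d[j] * nup * nvp)
        W[, j] <- sig * up / nup; H[j, ] <- sig * vp / nvp
      } else if (nun * nvn > 0) {
        sig <- sqrt(sv$d[j] * nun * nvn)
        W[, j] <- sig * un / nun; H[j, ] <- sig * vn / nvn
      }
    }
  }
  avg <- mean(B)
  W[W == 0] <- avg; H[H == 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorisation of an importance matrix
#'
#' Factorises B (samples x features, non-negative) as W H with k factors by
#' Frobenius multiplicative updates, and selects the factor whose sample
#' scores best separate the two classes (largest absolute standardised
#' rank-sum statistic of the W column between classes). Feature
#' contributions to each factor are the H rows normalised to sum to one.
#'
#' @param B Non-negative samples x features matrix (rows typically sum to 1).
#' @param labels Binary 0/1 class labels aligned to the rows of B.
#' @param k Rank (default 2).
#' @param seed Seed (used only by the `"random"` initialisation).
#' @param max_iter,tol Update iterations and relative-change stopping
#'   tolerance on the reconstruction error.
#' @param init `"nndsvda"` (deterministic SVD-based, default) or `"random"`.
#' @return List of class `"nmf_result"`: `W`, `H`, `k`, `objective` (the
#'   per-iteration Frobenius error trace, non-increasing), `recon_error`,
#'   `discriminative_factor`, `separation_stat` (per-factor statistics), and
#'   `contributions` (k x d, rows summing to 1).
#' @export
nmf_factorise <- function(B, labels, k = 2L, seed = 1L, max_iter = 200L,
                          tol = 1e-6, init = c("nndsvda", "random")) {
  .check_importance(B)
  init <- match.arg(init)
  n <- nrow(B); d <- ncol(B)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > min(n, d)) stop("k must be <= min(n, d)", call. = FALSE)
  labels <- as.numeric(labels)
  if (length(labels) != n || !all(labels %in% c(0, 1))) {
    stop("labels must be 0/1 and aligned to rows of B", call. = FALSE)
  }

  if (init == "nndsvda") {
    st <- .nndsvda(B, k)
  } else {
    withr::local_seed(seed)
    st <- list(W = matrix(runif(n * k, 1e-3, 1), n, k) * sqrt(mean(B) / k),
               H = matrix(runif(k * d, 1e-3, 1), k, d) * sqrt(mean(B) / k))
  }
  W <- st$W; H <- st$H
  eps <- 1e-10
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, B)) / (crossprod(W) %*% H + eps)
    W <- W * (B %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((B - W %*% H)^2))
    obj <- c(obj, err)
    if (is.finite(prev) && prev - err < tol * max(prev, 1e-12)) break
    prev <- err
  }

  z <- apply(W, 2L, .ranksum_z, labels = labels)
  contrib <- H / pmax(rowSums(H), eps)
  dimnames(W) <- list(rownames(B), paste0("factor", seq_len(k)))
  dimnames(H) <- list(paste0("factor", seq_len(k)), colnames(B))
  dimnames(contrib) <- dimnames(H)
  structure(list(W = W, H = H, k = as.integer(k), objective = obj,
                 recon_error = obj[length(obj)],
                 discriminative_factor = which.max(abs(z)),
                 separation_stat = z, contributions = contrib),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("NMF of importance matrix: k =", x$k,
      " recon error =", format(x$recon_error, digits = 4), "\n")
  cat("  discriminative factor:", x$discriminative_factor,
      " (|rank-sum z| =", format(abs(x$separation_stat[x$discriminative_factor]),
                                 digits = 3), ")\n")
  invisible(x)
}

#' Top feature contributions of an NMF factor
#'
#' @param fit An `nmf_result`.
#' @param factor Factor index (default: the discriminative factor).
#' @param n How many features.
#' @return Named numeric vector of relative contributions, decreasing.
#' @export
top_contributions <- function(fit, factor = fit$discriminative_factor, n = 10L) {
  v <- sort(fit$contributions[factor, ], decreasing = TRUE)
  head(v, n)
}

#' PCA ordination of an importance matrix
#'
#' Column-mean-centred, unscaled principal component analysis via singular
#' value decomposition. Importance scores share a common scale (rows sum to
#' one), so variables are not standardised; set `scale.` to override.
#'
#' @param B Samples x features matrix.
#' @param r Number of axes to keep.
#' @param scale. Standardise columns first (default `FALSE`).
#' @return List of class `"ordination"`: `scores` (n x r), `loadings`
#'   (d x r, orthonormal columns), `explained_variance_ratio` (length r,
#'   non-increasing), `center`, `feature_variance`.
#' @export
pca_ordinate <- function(B, r = 2L, scale. = FALSE) {
  if (nrow(B) < 3L) stop("need at least 3 samples for ordination", call. = FALSE)
  if (r > min(nrow(B), ncol(B))) stop("r exceeds min(n, d)", call. = FALSE)
  pc <- prcomp(B, center = TRUE, scale. = scale.)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  r_eff <- min(r, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(r_eff), drop = FALSE],
                 loadings = pc$rotation[, seq_len(r_eff), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(r_eff)],
                 center = pc$center,
                 feature_variance = apply(B, 2L, var)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("PCA ordination:", ncol(x$scores), "axes; variance explained ",
      paste(format(x$explained_variance_ratio, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Association of an ordination axis with clinical T/N/M stage
#'
#' Ordinary least squares of one axis's sample scores on dummy-coded tumour
#' (T), node (N) and metastasis (M) stage entered jointly as nominal
#' factors, with the lowest observed level of each as reference, optionally
#' restricted to one class (e.g. the luminal A samples only). Factors that
#' are constant within the subset are dropped with a warning.
#'
#' @param ord An `"ordination"` (or any matrix of axis scores with sample
#'   rownames).
#' @param clinical Data frame with columns `sample_id`, `T`, `N`, `M`
#'   (nominal stage codes such as "T1", "N0", "M0").
#' @param axis Which axis to model (default 1).
#' @param labels Optional binary labels named by (or aligned to) sample id,
#'   required when `subset_class` is given.
#' @param subset_class Optional label value; the model is fit on those
#'   samples only.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @return Data frame of class `"stage_association"`: one row per
#'   non-reference level, with columns `factor`, `level`, `estimate`,
#'   `p_value` (and `p_adj` if requested); attributes `axis` and `subset`.
#' @export
stage_association <- function(ord, clinical, axis = 1L, labels = NULL,
                              subset_class = NULL, adjust = FALSE) {
  scores <- if (inherits(ord, "ordination")) ord$scores else as.matrix(ord)
  if (axis > ncol(scores)) stop("axis exceeds the ordination rank", call. = FALSE)
  ids <- rownames(scores)
  if (is.null(ids)) stop("ordination scores must carry sample ids", call. = FALSE)
  clin <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  if (any(is.na(clin$sample_id))) {
    stop("clinical table is missing ", sum(is.na(clin$sample_id)), " scored sample(s)",
         call. = FALSE)
  }
  y <- scores[, axis]
  keep <- rep(TRUE, length(y))
  if (!is.null(subset_class)) {
    if (is.null(labels)) stop("subset_class requires labels", call. = FALSE)
    lab <- if (!is.null(names(labels))) labels[ids] else labels
    keep <- lab == subset_class
  }
  y <- y[keep]; clin <- clin[keep, , drop = FALSE]
  if (length(y) < 3L) stop("subset too small for a stage model", call. = FALSE)

  df <- data.frame(.y = y)
  used <- character(0)
  for (f in c("T", "N", "M")) {
    lev <- sort(unique(as.character(clin[[f]])))
    if (length(lev) >= 2L) {
      df[[f]] <- factor(as.character(clin[[f]]), levels = lev)
      used <- c(used, f)
    } else {
      warning("stage factor ", f, " is constant within the subset; dropped",
              call. = FALSE)
    }
  }
  if (length(used) == 0L) stop("all stage factors are constant in the subset", call. = FALSE)

  fit <- lm(stats::reformulate(used, response = ".y"), data = df)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  term <- rownames(sm)
  fac <- substr(term, 1L, 1L)
  out <- data.frame(factor = fac, level = substring(term, 2L),
                    estimate = sm[, "Estimate"],
                    p_value = sm[, "Pr(>|t|)"], row.names = NULL)
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  structure(out, class = c("stage_association", "data.frame"),
            axis = axis, subset = subset_class)
}

#' F1 score for the positive class
#'
#' @param truth 0/1 truth labels.
#' @param pred 0/1 predicted labels.
#' @return 2TP / (2TP + FP + FN); 0 when the denominator is 0.
#' @export
f1_score <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Baseline classifiers on the same split
#'
#' Fits an L2-regularised logistic regression (ridge penalty chosen by
#' cross-validation) and a linear soft-margin SVM on the training features
#' and reports the test-set F1 score of each, for side-by-side comparison
#' with the attention model. The same log1p / z-score transform the
#' attention model uses is applied by default.
#'
#' @param train_x,train_y Training matrix and 0/1 labels.
#' @param test_x,test_y Test matrix and 0/1 labels.
#' @param seed Seed for the cross-validation folds.
#' @param scale_features Apply the model's input transform (default `TRUE`).
#' @param cost SVM cost parameter (default 1).
#' @return Data frame with columns `model` and `f1`.
#' @export
run_baselines <- function(train_x, train_y, test_x, test_y, seed = 1L,
                          scale_features = TRUE, cost = 1) {
  train_y <- as.numeric(train_y); test_y <- as.numeric(test_y)
  if (length(unique(train_y)) < 2L) stop("training labels are degenerate", call. = FALSE)
  scaling <- .scale_learn(train_x, scale_features)
  Xtr <- .scale_apply(train_x, scaling)
  Xte <- .scale_apply(test_x, scaling)

  withr::local_seed(seed)
  cv <- glmnet::cv.glmnet(Xtr, train_y, family = "binomial", alpha = 0,
                          nfolds = 5)
  p_lr <- as.vector(predict(cv, Xte, s = "lambda.min", type = "response"))
  f1_lr <- f1_score(test_y, as.numeric(p_lr > 0.5))

  sv <- e1071::svm(Xtr, factor(train_y, levels = c(0, 1)), kernel = "linear",
                   cost = cost, scale = FALSE)
  pred_sv <- as.numeric(as.character(predict(sv, Xte)))
  f1_sv <- f1_score(test_y, pred_sv)

  data.frame(model = c("logistic", "svm"), f1 = c(f1_lr, f1_sv))
}

#' Per-feature two-class mean differences
#'
#' Welch two-sample t-test of each named feature between the classes.
#' `mean_diff` is mean(class 0) - mean(class 1), so a positive value means
#' the feature is higher in class 0 (the y = 0 class, e.g. luminal B).
#'
#' @param x Samples x features matrix (typically the test-set expression).
#' @param labels 0/1 labels aligned to rows.
#' @param feature_ids Features to test (default: all columns).
#' @return Data frame with per-feature means, `mean_diff`, `direction`
#'   (`"up_in_class0"` / `"up_in_class1"` / `"none"`), and `p_value`.
#' @export
group_mean_difference <- function(x, labels, feature_ids = colnames(x)) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  missing <- setdiff(feature_ids, colnames(x))
  if (length(missing)) {
    stop("feature(s) not found: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(feature_ids, function(f) {
    v0 <- x[labels == 0, f]; v1 <- x[labels == 1, f]
    diff <- mean(v0) - mean(v1)
    if (sd(v0) == 0 && sd(v1) == 0) {
      p <- if (diff == 0) 1 else 0
    } else {
      p <- t.test(v0, v1)$p.value
    }
    data.frame(feature = f, mean_class0 = mean(v0), mean_class1 = mean(v1),
               mean_diff = diff,
               direction = if (diff > 0) "up_in_class0"
                           else if (diff < 0) "up_in_class1" else "none",
               p_value = p)
  })
  do.call(rbind, rows)
}
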
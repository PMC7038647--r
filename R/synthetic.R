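# Synthetic RNA-seq-like cohorts with planted structure: two classes
# separated by a small set of discriminative features, and a subgroup of the
# positive class carrying a severity gradient tied to an ordinal stage
# covariate. Counts are negative-binomial with log-normal library sizes, so
# size-factor normalisation is non-trivial and the whole preprocessing /
# training / interpretation stack can be exercised without external data.

#' Configuration for a synthetic cohort
#'
#' @param n_per_class Samples per class (default 150).
#' @param n_features Total features d (default 500).
#' @param n_planted Discriminative features up-regulated in class B
#'   (label 0); default 10.
#' @param effect_size Log fold-change of the planted features in class B
#'   (default 2).
#' @param dispersion Negative-binomial overdispersion phi, so
#'   variance = mu + phi * mu^2 (default 0.4).
#' @param baseline_mean Median of the log-normal spread of per-feature
#'   baseline means (default 100).
#' @param subgroup_fraction Fraction of class-A samples carrying the
#'   severity gradient (default 0.5).
#' @param n_gradient Features whose mean shifts with stage inside the
#'   class-A subgroup (default 10; disjoint from the planted features).
#' @param gradient_effect Log-scale shift per stage increment for gradient
#'   features (default 1: a stage-4 subgroup member is shifted by 3 log
#'   units, comparable to the between-class effect).
#' @param libsize_sdlog Log-normal sd of the per-sample library-size
#'   multipliers (default 0.3).
#' @param stage_probs_a,stage_probs_b Stage 1-4 probabilities per class;
#'   class B is skewed toward higher stages, reflecting its worse prognosis.
#' @param seed Integer seed.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_per_class = 150L, n_features = 500L,
                             n_planted = 10L, effect_size = 2,
                             dispersion = 0.4, baseline_mean = 100,
                             subgroup_fraction = 0.5, n_gradient = 10L,
                             gradient_effect = 1, libsize_sdlog = 0.3,
                             stage_probs_a = c(0.45, 0.30, 0.20, 0.05),
                             stage_probs_b = c(0.15, 0.30, 0.35, 0.20),
                             seed = 1L) {
  stopifnot(n_per_class >= 2, n_features >= 1,
            n_planted >= 0, n_gradient >= 0,
            n_planted + n_gradient <= n_features,
            dispersion > 0, baseline_mean > 0,
            subgroup_fraction >= 0, subgroup_fraction <= 1,
            libsize_sdlog >= 0,
            length(stage_probs_a) == 4, length(stage_probs_b) == 4,
            abs(sum(stage_probs_a) - 1) < 1e-8,
            abs(sum(stage_probs_b) - 1) < 1e-8)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size, dispersion = dispersion,
                 baseline_mean = baseline_mean,
                 subgroup_fraction = subgroup_fraction,
                 n_gradient = as.integer(n_gradient),
                 gradient_effect = gradient_effect,
                 libsize_sdlog = libsize_sdlog,
                 stage_probs_a = stage_probs_a, stage_probs_b = stage_probs_b,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic two-class cohort
#'
#' Counts for sample j, feature i are negative-binomial with mean
#' `l_j * base_i * exp(class_effect + gradient_effect)` and the configured
#' dispersion, where `l_j` is a log-normal library-size multiplier and
#' `base_i` a log-normal baseline. Planted features get the class effect in
#' class B (label 0); gradient features get `gradient_effect * (stage - 1)`
#' inside the class-A severity subgroup, whose stages span 1-4. Class-A
#' samples outside the subgroup sit at the low stages (1-2), consistent
#' with carrying no severity shift; class B is skewed toward higher
#' stages. The clinical table codes stage as T1-T4 with correlated N and M
#' categories.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `"synthetic_cohort"`: `counts` (samples x features
#'   integer matrix), `labels` (named 0/1 vector; 1 = class A), `stage`
#'   (named integer 1-4), `clinical` (data frame `sample_id`, `T`, `N`,
#'   `M`, `subtype`), and `truth` (planted / gradient feature ids and
#'   indices, subgroup membership mask).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::local_seed(cfg$seed)
  n <- 2L * cfg$n_per_class
  d <- cfg$n_features
  sample_ids <- sprintf("S%04d", seq_len(n))
  feature_ids <- sprintf("G%04d", seq_len(d))

  labels <- setNames(rep(c(1, 0), each = cfg$n_per_class), sample_ids)  # 1 = class A
  planted <- if (cfg$n_planted > 0) seq_len(cfg$n_planted) else integer(0)
  gradient <- if (cfg$n_gradient > 0) cfg$n_planted + seq_len(cfg$n_gradient) else integer(0)

  # Severity-continuum subgroup of class A is drawn first: its members'
  # stages span 1-4 and their gradient features shift with stage. Class-A
  # samples off the continuum stay at the low stages — a high stage without
  # the corresponding feature shift would be a self-contradictory plant.
  subgroup <- rep(FALSE, n)
  a_idx <- which(labels == 1)
  n_sub <- round(length(a_idx) * cfg$subgroup_fraction)
  if (n_sub > 0) subgroup[sample(a_idx, n_sub)] <- TRUE
  names(subgroup) <- sample_ids

  stage <- integer(n)
  low_probs <- cfg$stage_probs_a[1:2] / sum(cfg$stage_probs_a[1:2])
  carriers <- labels == 1 & subgroup
  rest_a <- labels == 1 & !subgroup
  stage[carriers] <- sample(1:4, sum(carriers), TRUE, cfg$stage_probs_a)
  stage[rest_a] <- sample(1:2, sum(rest_a), TRUE, low_probs)
  stage[labels == 0] <- sample(1:4, sum(labels == 0), TRUE, cfg$stage_probs_b)
  names(stage) <- sample_ids

  base <- rlnorm(d, meanlog = log(cfg$baseline_mean), sdlog = 1)
  libsize <- rlnorm(n, meanlog = 0, sdlog = cfg$libsize_sdlog)

  # log-scale effect matrix
  eff <- matrix(0, n, d)
  if (length(planted)) eff[labels == 0, planted] <- cfg$effect_size
  if (length(gradient)) {
    carriers <- which(subgroup)
    if (length(carriers)) {
      eff[carriers, gradient] <- cfg$gradient_effect * (stage[carriers] - 1)
    }
  }
  mu <- libsize * sweep(exp(eff), 2L, base, "*")
  counts <- matrix(rnbinom(n * d, mu = as.vector(mu), size = 1 / cfg$dispersion),
                   n, d, dimnames = list(sample_ids, feature_ids))
  storage.mode(counts) <- "double"

  # clinical table: T codes the planted stage; N and M drawn with
  # stage-dependent rates so the three factors are realistically correlated
  n_lev <- ifelse(runif(n) < 0.15 * stage, 2L, ifelse(runif(n) < 0.25 * stage, 1L, 0L))
  m_lev <- ifelse(stage == 4 & runif(n) < 0.4, 1L, 0L)
  clinical <- data.frame(sample_id = sample_ids,
                         T = paste0("T", stage),
                         N = paste0("N", n_lev),
                         M = paste0("M", m_lev),
                         subtype = ifelse(labels == 1, "A", "B"))

  structure(list(counts = counts, labels = labels, stage = stage,
                 clinical = clinical,
                 truth = list(planted_idx = planted,
                              planted_features = feature_ids[planted],
                              gradient_idx = gradient,
                              gradient_features = feature_ids[gradient],
                              subgroup = subgroup),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$counts), "samples x", ncol(x$counts),
      "features;", length(x$truth$planted_idx), "planted,",
      length(x$truth$gradient_idx), "gradient features\n")
  invisible(x)
}

#' Generate a gene-set collection over a synthetic cohort
#'
#' Emits signal sets built around the planted features, random null sets,
#' at least one overlapping pair, and at least one set smaller than 10
#' members, so the size filter and aggregation can all be exercised.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_null Number of null sets (default 15).
#' @param null_size Members per null set (default 20).
#' @param seed Seed (default: the cohort's seed + 1).
#' @return A `gene_set_collection`.
#' @export
generate_gene_sets <- function(cohort, n_null = 15L, null_size = 20L,
                               seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  withr::local_seed(seed)
  feats <- colnames(cohort$counts)
  planted <- cohort$truth$planted_features
  null_pool <- setdiff(feats, planted)

  sets <- list()
  desc <- character(0)
  if (length(planted) >= 2) {
    # signal set: all planted features padded with nulls to pass the filter
    sets$SIG01 <- c(planted, sample(null_pool, max(0, 12 - length(planted))))
    desc["SIG01"] <- "signal: all planted features"
    # overlapping signal set sharing half of the planted features
    half <- planted[seq_len(ceiling(length(planted) / 2))]
    sets$SIG02 <- c(half, sample(null_pool, 12 - length(half)))
    desc["SIG02"] <- "signal: overlaps SIG01"
  }
  # a deliberately small set (< 10 members) to exercise the size filter
  sets$SMALL1 <- sample(null_pool, 5)
  desc["SMALL1"] <- "below the size-10 filter"
  for (i in seq_len(n_null)) {
    id <- sprintf("NULL%02d", i)
    sets[[id]] <- sample(null_pool, null_size)
    desc[id] <- "null set"
  }
  gene_set_collection(sets, descriptions = desc)
}
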
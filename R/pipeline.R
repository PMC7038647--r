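# End-to-end driver: preprocess -> split -> fit -> score the held-out test
# set -> interpret (NMF, PCA, stage models, baselines), writing every
# artefact plus a manifest that records the configuration and seeds so a run
# can be repeated exactly.

#' Split a cohort into train and test sets
#'
#' Fraction-based splits are stratified by class and seeded; explicit id
#' lists are validated and returned verbatim. When `patient_ids` is given,
#' every sample of any patient contributing more than one sample is removed
#' before splitting (one sample per patient).
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels 0/1 labels aligned to `sample_ids`.
#' @param test_fraction Fraction of each class set aside for testing
#'   (default 1/3); ignored when `test_ids` is supplied.
#' @param test_ids,train_ids Optional explicit id lists (must be disjoint;
#'   unmentioned samples go to the training set when only `test_ids` is
#'   given).
#' @param patient_ids Optional per-sample patient identifiers for the
#'   one-sample-per-patient rule.
#' @param seed Seed for the stratified draw.
#' @return List with `train` and `test` character vectors of sample ids.
#' @export
split_cohort <- function(sample_ids, labels, test_fraction = 1 / 3,
                         test_ids = NULL, train_ids = NULL,
                         patient_ids = NULL, seed = 1L) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(sample_ids))
  if (!is.null(patient_ids)) {
    stopifnot(length(patient_ids) == length(sample_ids))
    dup <- patient_ids %in% patient_ids[duplicated(patient_ids)]
    sample_ids <- sample_ids[!dup]
    labels <- labels[!dup]
  }
  if (!is.null(test_ids)) {
    if (is.null(train_ids)) train_ids <- setdiff(sample_ids, test_ids)
    if (length(intersect(train_ids, test_ids))) {
      stop("train and test id lists overlap", call. = FALSE)
    }
    bad <- setdiff(c(train_ids, test_ids), sample_ids)
    if (length(bad)) stop("unknown sample id(s): ", paste(head(bad, 5), collapse = ", "),
                          call. = FALSE)
    split <- list(train = train_ids, test = test_ids)
  } else {
    if (test_fraction <= 0 || test_fraction >= 1) {
      stop("test_fraction must be in (0, 1)", call. = FALSE)
    }
    withr::local_seed(seed)
    test <- character(0)
    for (cl in sort(unique(labels))) {
      ids <- sample_ids[labels == cl]
      n_test <- round(length(ids) * test_fraction)
      test <- c(test, sample(ids, n_test))
    }
    split <- list(train = setdiff(sample_ids, test), test = test)
  }
  for (part in c("train", "test")) {
    lab <- labels[match(split[[part]], sample_ids)]
    if (length(unique(lab)) < 2L) {
      stop("both classes must be present in the ", part, " set", call. = FALSE)
    }
  }
  split
}

#' Run the full pipeline on a cohort
#'
#' Preprocesses the counts (zero-feature filter, median-of-ratios
#' normalisation, optional gene-set aggregation), makes a stratified
#' train/test split, fits the attention classifier on the training samples,
#' scores importance on the withheld test samples only, and interprets the
#' importance matrix (NMF discriminative factor, PCA ordination,
#' stage-association models when clinical stages are provided, baseline
#' classifiers). All tables are written as TSV under `out_dir` together
#' with a JSON manifest of the configuration and seeds.
#'
#' @param counts Samples x genes raw count matrix.
#' @param labels Named (or aligned) 0/1 vector; 1 is the positive class.
#' @param out_dir Output directory (created if needed).
#' @param clinical Optional clinical data frame (`sample_id`, `T`, `N`,
#'   `M`).
#' @param gene_sets Optional `gene_set_collection`; when given the model
#'   runs in annotation space.
#' @param model_config A [triage_config()].
#' @param min_set_size Gene-set size filter (default 10).
#' @param test_fraction Held-out fraction per class (default 1/3).
#' @param patient_ids Optional per-sample patient ids (one sample per
#'   patient rule).
#' @param nmf_k NMF rank (default 2).
#' @param n_axes PCA axes to keep and test (default 2).
#' @param stage_subset_class Label value defining the subset for the stage
#'   models (default 1, the positive class).
#' @param seed Seed for the split (the model seed lives in `model_config`).
#' @param write_plots Also write figure files (requires a working graphics
#'   device; default `FALSE`).
#' @return Invisibly, a list with the split, model, importance matrix, and
#'   analysis results; all artefacts are also on disk under `out_dir`.
#' @export
run_pipeline <- function(counts, labels, out_dir, clinical = NULL,
                         gene_sets = NULL, model_config = triage_config(),
                         min_set_size = 10L, test_fraction = 1 / 3,
                         patient_ids = NULL, nmf_k = 2L, n_axes = 2L,
                         stage_subset_class = 1, seed = 1L,
                         write_plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "preprocess"
  result <- tryCatch({
    if (!is.null(names(labels))) labels <- labels[rownames(counts)]
    labels <- as.numeric(labels)
    prep <- preprocess_counts(counts, sets = gene_sets,
                              min_set_size = min_set_size)
    feats <- prep$features

    stage <- "split"
    split <- split_cohort(rownames(feats), labels,
                          test_fraction = test_fraction,
                          patient_ids = patient_ids, seed = seed)
    lab <- setNames(labels, rownames(feats))
    train_x <- feats[split$train, , drop = FALSE]
    test_x <- feats[split$test, , drop = FALSE]
    train_y <- lab[split$train]
    test_y <- lab[split$test]

    stage <- "fit"
    model <- triage_fit(train_x, train_y, model_config)

    stage <- "score"
    B <- score_importance(model, test_x)
    stopifnot(!any(rownames(B) %in% split$train))  # test-set-only convention
    write_expression(unclass(B), file.path(out_dir, "importance.tsv"))
    prob <- predict(model, test_x, type = "prob")
    f1_attn <- f1_score(test_y, as.numeric(prob > 0.5))

    stage <- "nmf"
    nmf <- nmf_factorise(unclass(B), labels = test_y, k = nmf_k,
                         seed = model_config$seed)
    contrib <- data.frame(feature = colnames(nmf$contributions),
                          t(nmf$contributions), check.names = FALSE)
    write.table(contrib, file.path(out_dir, "nmf_contributions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(nmf$W), nmf$W,
                           check.names = FALSE),
                file.path(out_dir, "nmf_sample_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "pca"
    ord <- pca_ordinate(unclass(B), r = n_axes)
    write.table(data.frame(sample_id = rownames(ord$scores), ord$scores,
                           check.names = FALSE),
                file.path(out_dir, "ordination_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(feature = rownames(ord$loadings), ord$loadings,
                           check.names = FALSE),
                file.path(out_dir, "ordination_loadings.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stage_association"
    assoc <- NULL
    if (!is.null(clinical)) {
      assoc <- do.call(rbind, lapply(seq_len(ncol(ord$scores)), function(ax) {
        a <- tryCatch(
          stage_association(ord, clinical, axis = ax, labels = test_y,
                            subset_class = stage_subset_class),
          error = function(e) NULL)
        if (is.null(a)) return(NULL)
        cbind(axis = ax, as.data.frame(a))
      }))
      if (!is.null(assoc)) {
        write.table(assoc, file.path(out_dir, "stage_associations.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    stage <- "baselines"
    bl <- run_baselines(train_x, train_y, test_x, test_y,
                        seed = model_config$seed)
    perf <- rbind(data.frame(model = "attention", f1 = f1_attn), bl)
    write.table(perf, file.path(out_dir, "f1_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (write_plots) {
      stage <- "plots"
      try({
        ggplot2::ggsave(file.path(out_dir, "factor_contributions.png"),
                        plot_factor_contributions(nmf), width = 6, height = 4, dpi = 120)
        ggplot2::ggsave(file.path(out_dir, "factor_scores.png"),
                        plot_factor_scores(nmf, test_y), width = 4, height = 4, dpi = 120)
        ggplot2::ggsave(file.path(out_dir, "biplot.png"),
                        plot_biplot(ord, labels = test_y), width = 6, height = 5, dpi = 120)
      }, silent = TRUE)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(packageVersion("exprattn")),
      r_version = R.version.string,
      seed_split = seed,
      model_config = unclass(model_config),
      feature_space = if (is.null(gene_sets)) "genes" else "annotations",
      n_train = length(split$train), n_test = length(split$test),
      n_features = ncol(feats),
      f1 = setNames(as.list(perf$f1), perf$model),
      nmf = list(k = nmf_k, discriminative_factor = nmf$discriminative_factor),
      outputs = list.files(out_dir)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    list(split = split, model = model, importance = B, nmf = nmf,
         ordination = ord, associations = assoc, performance = perf,
         size_factors = prep$size_factors)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
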
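# Count preprocessing: zero-feature filtering, median-of-ratios size factors,
# normalisation, and engineering of annotation-level (gene-set) features by
# summing member genes.

#' Drop features with zero counts in every sample
#'
#' @param counts Samples x features count matrix.
#' @return The matrix restricted to features whose column sum is positive,
#'   column order preserved.
#' @export
drop_zero_features <- function(counts) {
  validate_expression(counts, "counts")
  keep <- colSums(counts) > 0
  if (!any(keep)) stop("all features have zero counts: empty feature space", call. = FALSE)
  counts[, keep, drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Effective library-size factors computed as the per-sample median of ratios
#' to a per-feature geometric-mean reference. The geometric mean is taken in
#' log space; features with any zero count are excluded from the reference,
#' so only all-positive features contribute. The factors are rescaled to
#' unit geometric mean, which leaves all factor ratios untouched but makes
#' normalisation idempotent: a normalised matrix re-estimates to factors of
#' exactly 1.
#'
#' @param counts Samples x features count matrix.
#' @return Named numeric vector of positive size factors, one per sample,
#'   with geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  validate_expression(counts, "counts")
  logc <- log(counts)                      # -Inf where count == 0
  loggeo <- colMeans(logc)                 # -Inf if any zero in that feature
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    stop("no feature has all-positive counts: the geometric-mean reference ",
         "is not computable", call. = FALSE)
  }
  logsf <- apply(logc[, usable, drop = FALSE], 1L, function(lr) {
    median(lr - loggeo[usable])
  })
  sf <- exp(logsf - mean(logsf))   # unit geometric mean
  names(sf) <- rownames(counts)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size-factor estimation produced non-positive factors", call. = FALSE)
  }
  sf
}

#' Divide each sample by its size factor
#'
#' @param counts Samples x features count matrix.
#' @param factors Named numeric vector from [estimate_size_factors()]; names
#'   must match the matrix's sample ids (any order).
#' @return Normalised matrix of the same shape.
#' @export
normalize_counts <- function(counts, factors) {
  validate_expression(counts, "counts")
  if (is.null(names(factors)) || !setequal(names(factors), rownames(counts))) {
    stop("size factors do not align with the matrix's samples", call. = FALSE)
  }
  f <- factors[rownames(counts)]
  if (any(!is.finite(f)) || any(f <= 0)) stop("size factors must be positive", call. = FALSE)
  counts / f
}

#' Filter gene sets against a measured feature universe
#'
#' Members outside `universe` are dropped first; sets whose remaining size is
#' below `min_size` are then removed. Counting measured members only makes the
#' filter a property of the data actually at hand.
#'
#' @param sets A `gene_set_collection`.
#' @param universe Character vector of measured feature ids.
#' @param min_size Minimum number of in-universe members to retain a set
#'   (default 10).
#' @return Filtered `gene_set_collection`, order preserved.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10L) {
  if (!inherits(sets, "gene_set_collection")) {
    sets <- gene_set_collection(sets)
  }
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  trimmed <- lapply(sets, function(m) m[m %in% universe])
  keep <- lengths(trimmed) >= min_size
  if (!any(keep)) {
    stop("no gene set has >= ", min_size, " measured members; ",
         "consider a smaller min_size", call. = FALSE)
  }
  gene_set_collection(trimmed[keep],
                      descriptions = attr(sets, "descriptions")[keep])
}

#' Aggregate gene-level values to annotation-level features
#'
#' Each output feature is a gene set; its value for a sample is the sum of the
#' member genes' values. Genes belonging to several sets contribute to each.
#' Sets are expected to be pre-filtered against the matrix's feature universe
#' (see [filter_gene_sets()]).
#'
#' @param x Samples x genes matrix (normalised counts by default in the
#'   pipeline, but any non-negative matrix is accepted).
#' @param sets A `gene_set_collection` whose members all appear in
#'   `colnames(x)`.
#' @return Samples x sets matrix, set order preserved.
#' @export
aggregate_to_annotations <- function(x, sets) {
  validate_expression(x)
  if (!inherits(sets, "gene_set_collection")) sets <- gene_set_collection(sets)
  missing <- lapply(sets, function(m) m[!m %in% colnames(x)])
  n_missing <- lengths(missing)
  if (any(n_missing == lengths(sets))) {
    stop("gene set(s) ", paste(names(sets)[n_missing == lengths(sets)], collapse = ", "),
         " reference no measured gene; run filter_gene_sets() first", call. = FALSE)
  }
  if (any(n_missing > 0)) {
    stop("gene set(s) ", paste(names(sets)[n_missing > 0], collapse = ", "),
         " contain unmeasured genes; run filter_gene_sets() first", call. = FALSE)
  }
  out <- vapply(sets, function(m) {
    rowSums(x[, m, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), names(sets)))
  out
}

#' Full count preprocessing
#'
#' Convenience wrapper: drop all-zero features, estimate size factors,
#' normalise, and (optionally) aggregate to annotation-level features.
#'
#' @param counts Samples x genes raw count matrix.
#' @param sets Optional `gene_set_collection`; when supplied the result is in
#'   annotation space.
#' @param min_set_size Minimum measured members per retained set (default 10).
#' @param aggregate_raw If `TRUE`, gene-set sums are taken on raw counts and
#'   normalised afterwards; default sums normalised values.
#' @return List with `features` (the model-ready matrix), `size_factors`, and
#'   `sets` (the filtered collection, or `NULL`).
#' @export
preprocess_counts <- function(counts, sets = NULL, min_set_size = 10L,
                              aggregate_raw = FALSE) {
  counts <- drop_zero_features(counts)
  sf <- estimate_size_factors(counts)
  norm <- normalize_counts(counts, sf)
  if (is.null(sets)) {
    return(list(features = norm, size_factors = sf, sets = NULL))
  }
  sets <- filter_gene_sets(sets, colnames(counts), min_size = min_set_size)
  feats <- if (aggregate_raw) {
    normalize_counts(aggregate_to_annotations(counts, sets), sf)
  } else {
    aggregate_to_annotations(norm, sets)
  }
  list(features = feats, size_factors = sf, sets = sets)
}
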
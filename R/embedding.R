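#' Build a fixed random feature-embedding matrix
#'
#' Each feature i receives a fixed m-dimensional identity vector e_i; the
#' embedded value of a feature for a sample is the multiplicative interaction
#' x_ji * e_i. The embedding is never trained: random vectors perform
#' comparably to learned ones for this architecture, and keeping them fixed
#' removes d x m parameters from the optimisation. Entries are i.i.d.
#' N(0, 1/m), so the norm of an embedded value is comparable across choices
#' of m.
#'
#' @param d Number of features (rows).
#' @param m Embedding dimension (columns); typically m << d.
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   matrix exactly.
#' @return A d x m numeric matrix with attributes `seed` and `distribution`.
#' @export
build_embedding <- function(d, m, seed = 1L) {
  if (d < 1 || m < 1) stop("embedding dimensions must be positive", call. = FALSE)
  withr::local_seed(seed)
  E <- matrix(rnorm(d * m, mean = 0, sd = 1 / sqrt(m)), nrow = d, ncol = m)
  structure(E, seed = as.integer(seed),
            distribution = list(name = "normal", mean = 0, sd = 1 / sqrt(m)))
}

#' Embed one sample into feature-embedding space
#'
#' Row i of the result is x_ji * e_i: a zero expression value embeds to the
#' zero vector, and the map is linear in the expression vector.
#'
#' @param x Numeric vector of length d (one sample's feature values).
#' @param E Embedding matrix from [build_embedding()] (d x m).
#' @return d x m matrix of embedded feature vectors.
#' @export
embed_sample <- function(x, E) {
  if (length(x) != nrow(E)) {
    stop("sample length (", length(x), ") does not match embedding rows (",
         nrow(E), ")", call. = FALSE)
  }
  as.vector(x) * E
}
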
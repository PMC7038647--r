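# Shared fixtures, all built in code at test time.

# Small count matrix with readable dimnames.
toy_counts <- function(values, n, d, samples = sprintf("s%d", seq_len(n)),
                       features = sprintf("g%d", seq_len(d))) {
  matrix(values, n, d, byrow = TRUE, dimnames = list(samples, features))
}

# 3 samples x 5 features toy matrix used for the size-factor oracle.
sf_toy <- function() {
  toy_counts(c(10, 20, 5, 100, 1,
               20, 40, 10, 200, 2,
               10, 10, 20, 100, 4), 3, 5)
}

# A tiny untrained model with reproducible random weights, for testing the
# per-sample stage functions against independent computations.
make_toy_model <- function(d = 6L, m = 4L, p = 3L, ha = 3L, hy = 3L,
                           seed = 42L, scale_features = FALSE) {
  cfg <- triage_config(m = m, p = p, alpha_hidden = ha, y_hidden = hy,
                       seed = seed, scale_features = scale_features)
  E <- build_embedding(d, m, seed = seed)
  withr::local_seed(seed + 1L)
  par <- exprattn:::nn_init_params(m, p, ha, hy)
  bn <- list(mean = rnorm(hy, sd = 0.1), var = runif(hy, 0.5, 1.5))
  structure(list(par = par, bn = bn, embedding = E, config = cfg,
                 scaling = list(enabled = scale_features,
                                center = NULL, scale = NULL),
                 features = sprintf("g%d", seq_len(d)),
                 training_log = data.frame(epoch = integer(0),
                                           loss = numeric(0),
                                           val_loss = numeric(0))),
            class = "triage_model")
}

# Small, clearly separable cohort for fast learning tests.
quick_cohort <- function(seed = 5L) {
  generate_cohort(synthetic_config(n_per_class = 40L, n_features = 60L,
                                   n_planted = 6L, effect_size = 2,
                                   n_gradient = 0L, subgroup_fraction = 0,
                                   seed = seed))
}

# Fast model settings for tests that only need a trained object.
quick_config <- function(seed = 1L, epochs = 15L, ...) {
  triage_config(m = 16L, p = 8L, alpha_hidden = 8L, y_hidden = 4L,
                epochs = epochs, batch_size = 16L, learning_rate = 0.01,
                seed = seed, ...)
}
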
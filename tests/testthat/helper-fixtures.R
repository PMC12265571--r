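# Shared test fixtures. Property checks run under a cheaper variant of
# the package's study conditions: full-size priors rescaled by alpha = 25
# (110 kb regions, 10 kb subwindows) over a constant diploid population,
# simulated at a scaled-down size.

test_priors <- function() rescale_region(parameter_priors(), 25)
test_demography <- function() demography(0, 250000)

# build a class_posterior data.frame from a plain matrix of 5 columns
as_posterior <- function(m, window_id = sprintf("w%d", seq_len(nrow(m)))) {
  out <- data.frame(window_id = window_id, p_hard = m[, 1],
                    p_hard_linked = m[, 2], p_soft = m[, 3],
                    p_soft_linked = m[, 4], p_neutral = m[, 5])
  class(out) <- c("class_posterior", "data.frame")
  out
}

# the scaled-down simulated training run used by the classifier-recovery
# checks; computed once per test session and cached
demo_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(seed = 20260901L,
                        train_config = training_config(seed = 20260901L))
      cache <<- run_end_to_end(cfg, file.path(tempdir(), "demo_run"),
                               quiet = TRUE)
    }
    cache
  }
})

# five well-separated Gaussian blobs in feature space: a linearly
# separable oracle for the classifier
blob_data <- function(n_per_class, d = 132L, sep = 6, seed = 99L) {
  set.seed(seed)
  centers <- matrix(0, 5, d)
  for (i in 1:5) centers[i, ((i - 1) * 20 + 1):(i * 20)] <- sep
  x <- do.call(rbind, lapply(1:5, function(i)
    matrix(rnorm(n_per_class * d), ncol = d) +
      matrix(centers[i, ], n_per_class, d, byrow = TRUE)))
  y <- factor(rep(sweep_classes(), each = n_per_class),
              levels = sweep_classes())
  list(x = x, y = y)
}
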
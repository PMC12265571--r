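# Simulator contracts and population-genetic expectations. Small
# populations and short regions keep these runs quick; the full
# desk-scale conditions are exercised by the recovery suite.

small_priors <- function(region = 50000L) {
  pr <- parameter_priors()
  rescale_region(pr, pr$region_length_bp / region)
}

test_that("neutral runs match Watterson's expected segregating-site count", {
  pr <- small_priors()
  dem <- demography(0, 20000)
  n_dip <- 5L
  set.seed(101)
  S <- theta <- numeric(250)
  for (i in 1:250) {
    r <- simulate_replicate("neutral", pr, dem, n_individuals = n_dip,
                            sim_n = 50)
    S[i] <- ncol(r$window$dosages)
    theta[i] <- 4 * dem$sizes[1] * r$params$mu * pr$region_length_bp
  }
  a_n <- sum(1 / seq_len(2 * n_dip - 1))
  expected <- mean(theta) * a_n
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("hard sweeps fix the beneficial allele and erode focal diversity", {
  pr <- test_priors()
  dem <- test_demography()
  set.seed(202)
  pi_focal <- pi_edge <- numeric(100)
  for (i in 1:100) {
    pd <- draw_params(pr, "hard")
    pd$s <- pr$s_high   # top of the selection range
    r <- simulate_replicate("hard", pr, dem, params = pd,
                            n_individuals = 10L, sim_n = 100)
    # conditioning contract: the beneficial allele is fixed in the sample
    expect_equal(r$n_beneficial_sampled, 20L)
    f <- compute_features(r$window)
    pi_focal[i] <- f["pi", 6]
    pi_edge[i] <- mean(f["pi", c(1, 11)])
  }
  expect_lt(mean(pi_focal), mean(pi_edge))
})

test_that("soft sweeps retain more diplotype structure than hard sweeps", {
  pr <- test_priors()
  dem <- test_demography()
  set.seed(303)
  # matched at the top of the s range, where the sweep erodes enough
  # diversity for the diplotype spectrum to be informative
  h2h1 <- list(hard = numeric(150), soft = numeric(150))
  for (label in names(h2h1)) {
    for (i in 1:150) {
      pd <- draw_params(pr, label)
      pd$s <- pr$s_high
      if (label == "soft") pd$f0 <- max(pd$f0, 0.02)
      r <- simulate_replicate(label, pr, dem, params = pd,
                              n_individuals = 10L, sim_n = 100)
      dos <- subwindow_dosages(r$window, 6)
      h2h1[[label]][i] <- h_stats(diplotype_spectrum(dos)$freq)["h2_h1"]
    }
  }
  expect_gt(mean(h2h1$soft), mean(h2h1$hard))
})

test_that("sweep placement follows the drawn subwindow", {
  pr <- test_priors()
  dem <- test_demography()
  set.seed(404)
  pd <- draw_params(pr, "hard-linked")
  r <- simulate_replicate("hard-linked", pr, dem, params = pd,
                          n_individuals = 5L, sim_n = 50)
  sw_len <- pr$region_length_bp / pr$n_subwindows
  expect_gte(r$params$sweep_position_bp,
             pd$sweep_subwindow_index * sw_len)
  expect_lt(r$params$sweep_position_bp,
            (pd$sweep_subwindow_index + 1) * sw_len)
})

test_that("identical seed and configuration give byte-identical replicates", {
  pr <- small_priors()
  dem <- demography(0, 10000)
  gen <- function() {
    set.seed(77)
    simulate_replicate("soft", pr, dem, n_individuals = 5L, sim_n = 50)
  }
  r1 <- gen()
  r2 <- gen()
  expect_identical(r1$window$dosages, r2$window$dosages)
  expect_identical(r1$window$positions_bp, r2$window$positions_bp)
  expect_identical(r1$params, r2$params)
})

test_that("infeasible f0 raises a parameter error", {
  pr <- small_priors()
  dem <- demography(0, 10000)
  pd <- draw_params(pr, "soft", rng_seed = 5)
  pd$f0 <- 1e-4   # f0 * 2 * sim_n < 1
  expect_error(simulate_replicate("soft", pr, dem, params = pd,
                                  n_individuals = 5L, sim_n = 50),
               "f0")
})

test_that("masking hides intervals, drops dead sites, and is idempotent", {
  set.seed(55)
  dos <- random_dosage_matrix(6, 20)
  pos <- sort(sample(0:299, 20))
  win <- genotype_window(dos, pos, 300, n_subwindows = 3L)

  expect_identical(apply_mask(win, mask_profile()), win)

  all_mask <- mask_profile(0, 300)
  expect_equal(ncol(apply_mask(win, all_mask)$dosages), 0L)

  sub1 <- mask_profile(100, 200)   # exactly the middle subwindow
  masked <- apply_mask(win, sub1)
  expect_true(all(masked$positions_bp < 100 | masked$positions_bp >= 200))
  expect_identical(apply_mask(masked, sub1), masked)
})

test_that("stratified class sets are disjoint with exact per-class counts", {
  pr <- small_priors()
  dem <- demography(0, 10000)
  set.seed(66)
  reps <- list()
  for (cl in sweep_classes())
    reps <- c(reps, simulate_class_set(cl, pr, dem, 12L,
                                       n_individuals = 4L, sim_n = 50))
  sets <- build_class_sets(reps, 8L, 3L, rng_seed = 9L)
  expect_length(sets$train, 40L)
  expect_length(sets$test, 15L)
  expect_length(intersect(attr(sets, "train_idx"),
                          attr(sets, "test_idx")), 0L)
  for (cl in sweep_classes()) {
    expect_equal(sum(vapply(sets$train, `[[`, "", "label") == cl), 8L)
    expect_equal(sum(vapply(sets$test, `[[`, "", "label") == cl), 3L)
  }
  expect_error(build_class_sets(reps, 10L, 5L), "insufficient")

  empty_test <- build_class_sets(reps, 8L, 0L)
  expect_length(empty_test$test, 0L)
  expect_length(empty_test$train, 40L)
})

test_that("replicates round-trip through gzipped text serialization", {
  pr <- small_priors()
  dem <- demography(0, 10000)
  set.seed(88)
  reps <- list(simulate_replicate("neutral", pr, dem, n_individuals = 4L,
                                  sim_n = 50),
               simulate_replicate("hard", pr, dem, n_individuals = 4L,
                                  sim_n = 50))
  reps[[1]] <- apply_mask(reps[[1]], mask_profile(1000, 5000))
  dir <- tempfile()
  paths <- write_replicates(reps, dir)
  back <- read_replicates(paths)
  for (i in seq_along(reps)) {
    expect_identical(back[[i]]$label, reps[[i]]$label)
    expect_equal(back[[i]]$window$dosages, reps[[i]]$window$dosages,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$window$positions_bp,
                 reps[[i]]$window$positions_bp)
    expect_equal(back[[i]]$params$mu, reps[[i]]$params$mu)
    expect_equal(back[[i]]$params$s, reps[[i]]$params$s)
  }
})
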
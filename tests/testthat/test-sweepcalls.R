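test_that("sweep calling applies the argmax and combined-probability rules", {
  m <- rbind(c(0.50, 0.02, 0.46, 0.01, 0.01),   # hard call at 0.96
             c(0.50, 0.05, 0.40, 0.04, 0.01),   # 0.90 < 0.95: no call
             c(0.24, 0.01, 0.25, 0.01, 0.49))   # argmax neutral: never
  post <- as_posterior(m)
  calls <- call_sweeps(post, 0.95)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$called_class, "hard")
  expect_equal(calls$combined_sweep_prob, 0.96)

  expect_equal(nrow(call_sweeps(post, 0.8)), 2L)
  expect_equal(nrow(call_sweeps(post[3, ], 0)), 0L)
})

test_that("q-values follow the neutral-null FDR with step-up monotonization", {
  calls <- call_sweeps(as_posterior(rbind(
    c(0.9, 0, 0.08, 0, 0.02),
    c(0.7, 0, 0.1, 0, 0.2),
    c(0.5, 0, 0.1, 0, 0.4))), 0)

  # no neutral simulation reaches any call's threshold: all q = 0
  res <- fdr_and_q(calls, neutral_scores = rep(0.1, 1000),
                   n_windows_scanned = 5000)
  expect_equal(res$q_value, c(0, 0, 0))

  # 10 of 1000 neutral sims called at the single threshold, 50 calls,
  # 5000 windows: E = 50, FDR capped at 1
  many <- as_posterior(matrix(rep(c(0.5, 0, 0.45, 0, 0.05), each = 50),
                              nrow = 50))
  calls50 <- call_sweeps(many, 0)
  neutral <- c(rep(0.96, 10), rep(0.1, 990))
  res50 <- fdr_and_q(calls50, neutral, 5000)
  expect_equal(unique(res50$fdr), 1)
  expect_equal(unique(res50$q_value), 1)

  # step-up: FDR 0.3 at the lower threshold pulls the higher one down
  two <- call_sweeps(as_posterior(rbind(
    c(0.6, 0, 0.3, 0, 0.1),     # prob 0.9
    c(0.5, 0, 0.2, 0, 0.3))), 0) # prob 0.7
  # craft a null giving FDR 0.5 at t=0.9 and 0.3 at t=0.7
  null_scores <- c(rep(0.95, 5), rep(0.8, 1), rep(0, 994))
  # at t=0.9: 5/1000 * 100 = 0.5 expected, 1 call -> FDR 0.5
  # at t=0.7: 6/1000 * 100 = 0.6 expected, 2 calls -> FDR 0.3
  res2 <- fdr_and_q(two, null_scores, 100)
  expect_equal(res2$fdr, c(0.5, 0.3))
  expect_equal(res2$q_value, c(0.3, 0.3))

  # q is monotone non-increasing in the combined sweep probability
  set.seed(19)
  m <- matrix(runif(250), ncol = 5)
  m <- m / rowSums(m)
  calls_r <- call_sweeps(as_posterior(m), 0)
  res_r <- fdr_and_q(calls_r, runif(200), 1000)
  expect_true(all(diff(res_r$q_value) >= 0))   # sorted by decreasing prob

  empty <- fdr_and_q(calls_r[0, ], runif(10), 100)
  expect_equal(nrow(empty), 0L)
})

test_that("the conservative soft-fraction correction reproduces its arithmetic", {
  # zero-error identity: uncorrected proportion
  est <- soft_fraction_corrected(1, 23, q_at_t = 0, c_hh = 0.9, c_hs = 0)
  expect_equal(est$proportion_soft, 23 / 24)

  # worked example of the formula
  est2 <- soft_fraction_corrected(4, 61, q_at_t = 0.04, c_hh = 0.88,
                                  c_hs = 0.07)
  expect_equal(est2$expected_false_discoveries, 2.6)
  expect_equal(est2$soft_adjusted, 61 - 2.6 - 4 / 0.88 * 0.07)
  expect_equal(est2$hard_adjusted, 4 + 4 / 0.88 * 0.07)
  expect_equal(est2$proportion_soft, 0.9308, tolerance = 1e-4)

  # no hard calls at all
  est3 <- soft_fraction_corrected(0, 10, 0, c_hh = 0.9, c_hs = 0.05)
  expect_equal(est3$proportion_soft, 1)

  expect_error(soft_fraction_corrected(5, 10, 0, c_hh = 0, c_hs = 0.1),
               "calibration")
})

test_that("the correction is monotone in q and in the hard-to-soft error", {
  base <- soft_fraction_corrected(5, 50, 0.05, 0.85, 0.05)$proportion_soft
  for (q in c(0.1, 0.2, 0.4)) {
    p <- soft_fraction_corrected(5, 50, q, 0.85, 0.05)$proportion_soft
    expect_lte(p, base)
  }
  for (chs in c(0.1, 0.2, 0.3)) {
    p <- soft_fraction_corrected(5, 50, 0.05, 0.85, chs)$proportion_soft
    expect_lte(p, base)
  }
  # bounds from the type invariants
  est <- soft_fraction_corrected(5, 50, 0.05, 0.85, 0.05)
  expect_lte(est$soft_adjusted, 50)
  expect_lte(est$proportion_soft, 50 / 55)
})

test_that("percent_soft reproduces reference hard/soft count percentages", {
  cells <- list(list(8, 157, 95.2), list(8, 355, 97.8), list(8, 71, 89.9),
                list(5, 145, 96.7), list(1, 23, 95.8), list(4, 61, 93.9),
                list(2, 15, 88.2), list(0, 3, 100), list(4, 75, 94.9),
                list(0, 66, 100), list(5, 37, 88.1), list(5, 149, 96.8),
                list(1, 44, 97.8), list(0, 36, 100), list(4, 24, 85.7),
                list(4, 90, 95.7), list(0, 18, 100), list(0, 6, 100),
                list(0, 3, 100), list(1, 21, 95.5))
  for (cell in cells)
    expect_equal(percent_soft(cell[[1]], cell[[2]]), cell[[3]])
  expect_true(is.na(percent_soft(0, 0)))
})

test_that("count_table tallies hard and soft calls per threshold", {
  m <- rbind(c(0.97, 0.01, 0.01, 0.005, 0.005),  # hard 0.98
             c(0.01, 0.01, 0.90, 0.04, 0.04),    # soft 0.91
             c(0.45, 0.02, 0.40, 0.03, 0.10),    # hard 0.85
             c(0.05, 0.05, 0.05, 0.05, 0.80))    # neutral
  tab <- count_table(list(popA = as_posterior(m)),
                     thresholds = c(0, 0.9, 0.95))
  expect_equal(tab$n_hard, c(2, 1, 1))
  expect_equal(tab$n_soft, c(1, 1, 0))
  expect_equal(tab$percent_soft, c(33.3, 50, 0))
})

test_that("sharing reports partition distinct windows by sample subset", {
  mk <- function(ids) data.frame(window_id = ids)
  one <- sharing_report(list(A = mk(c("w1", "w2"))))
  expect_equal(one$subset, "A")
  expect_equal(one$count, 2L)

  two <- sharing_report(list(A = mk(c("w1", "w2", "w3")),
                             B = mk(c("w1", "w4", "w5"))))
  expect_equal(two$count[two$subset == "A+B"], 1L)
  expect_equal(two$count[two$subset == "A"], 2L)
  expect_equal(two$count[two$subset == "B"], 2L)
  expect_equal(sum(two$count), 5L)
  expect_equal(sum(two$percent), 100)

  empty <- sharing_report(list(A = mk(character(0)), B = mk(character(0))))
  expect_equal(nrow(empty), 0L)
})
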
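test_that("confusion matrices match hand counts and the uncertain rule", {
  m <- rbind(c(0.80, 0.05, 0.05, 0.05, 0.05),   # hard, sweep prob 0.85
             c(0.05, 0.80, 0.05, 0.05, 0.05),   # hard-linked
             c(0.30, 0.05, 0.40, 0.05, 0.20),   # soft, sweep prob 0.70
             c(0.05, 0.05, 0.05, 0.80, 0.05),   # soft-linked
             c(0.05, 0.05, 0.05, 0.05, 0.80),   # neutral
             c(0.50, 0.00, 0.20, 0.10, 0.20))   # hard, sweep prob 0.70
  truth <- c("hard", "hard-linked", "soft", "soft-linked", "neutral",
             "hard")
  post <- as_posterior(m)

  cm0 <- confusion_at_threshold(post, truth, 0)
  expect_equal(sum(cm0$counts), 6)            # nothing uncertain at t = 0
  expect_equal(sum(cm0$n_uncertain), 0)
  expect_equal(cm0$counts["hard", "hard"], 2)
  expect_equal(rowSums(cm0$fractions)[c("hard", "soft")],
               c(hard = 1, soft = 1))

  # at t = 0.8 the two windows with sweep prob 0.70 become uncertain
  cm8 <- confusion_at_threshold(post, truth, 0.8)
  expect_equal(sum(cm8$counts), 4)
  expect_equal(unname(cm8$n_uncertain[c(1, 3)]), c(1L, 1L))
  expect_equal(cm8$counts["hard", "hard"], 1)

  # an argmax-soft example with sweep prob 0.7 < 0.8 is omitted
  one <- as_posterior(rbind(c(0.25, 0.05, 0.45, 0.05, 0.20)))
  cm1 <- confusion_at_threshold(one, "soft", 0.8)
  expect_equal(sum(cm1$counts), 0)
  expect_equal(sum(cm1$n_uncertain), 1)

  expect_error(confusion_at_threshold(post[0, ], character(0), 0),
               "empty")
})

test_that("raising the threshold never adds classified sweep examples", {
  set.seed(14)
  m <- matrix(runif(500), ncol = 5)
  m <- m / rowSums(m)
  post <- as_posterior(m)
  truth <- sample(sweep_classes(), 100, replace = TRUE)
  prev <- Inf
  for (t in c(0, 0.3, 0.6, 0.8, 0.9, 0.99)) {
    cm <- confusion_at_threshold(post, truth, t)
    n_sweep_classified <- sum(cm$counts[, c("hard", "soft")])
    expect_lte(n_sweep_classified, prev)
    prev <- n_sweep_classified
  }
  cm0 <- confusion_at_threshold(post, truth, 0)
  expect_equal(sum(cm0$counts), 100)
})

test_that("ROC/PR agree with hand-computed operating points", {
  # perfect separation
  m <- rbind(c(0.9, 0.025, 0.05, 0.02, 0.005),
             c(0.05, 0.02, 0.90, 0.02, 0.01),
             c(0.10, 0.30, 0.10, 0.30, 0.20),
             c(0.05, 0.05, 0.05, 0.05, 0.80))
  truth <- c("hard", "soft", "hard-linked", "neutral")
  res <- roc_pr(as_posterior(m), truth)
  expect_equal(res$auc, 1)
  expect_equal(res$ap, 1)

  # all scores identical: chance AUC
  m2 <- matrix(0.2, nrow = 6, ncol = 5)
  truth2 <- c("hard", "soft", "neutral", "neutral", "hard-linked",
              "soft-linked")
  res2 <- roc_pr(as_posterior(m2), truth2)
  expect_equal(res2$auc, 0.5)

  # one inversion among six examples: brute-force trapezoid value
  scores <- c(0.9, 0.8, 0.6, 0.7, 0.3, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  m3 <- cbind(scores, 0, 0, 0, 1 - scores)
  truth3 <- ifelse(labels, "hard", "neutral")
  res3 <- roc_pr(as_posterior(m3), truth3)
  # hand count: of the 9 (pos, neg) pairs, 8 rank correctly
  expect_equal(res3$auc, 8 / 9)

  expect_error(roc_pr(as_posterior(m2[1:2, ]), c("hard", "soft")),
               "required")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(25)
  raw <- runif(40)
  truth <- sample(c("hard", "neutral"), 40, replace = TRUE)
  truth[1:2] <- c("hard", "neutral")   # ensure both meta-classes
  build <- function(score) as_posterior(cbind(score, 0, 0, 0, 1 - score))
  a1 <- roc_pr(build(raw), truth)$auc
  a2 <- roc_pr(build(raw^3), truth)$auc
  a3 <- roc_pr(build(plogis(5 * raw)), truth)$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("AUC matches an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(36)
  score <- runif(60)
  truth <- sample(c("soft", "soft-linked"), 60, replace = TRUE)
  truth[1:2] <- c("soft", "soft-linked")
  post <- as_posterior(cbind(score / 2, 0, score / 2, 0, 1 - score))
  ours <- roc_pr(post, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth == "soft", predictor = score, quiet = TRUE,
    levels = c(FALSE, TRUE), direction = "<")))
  expect_equal(ours, ref)
})
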
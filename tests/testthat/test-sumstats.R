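test_that("pi matches enumeration of allele-copy pairs", {
  # one site, two diploids both heterozygous: 4 of 6 copy pairs differ
  expect_equal(pi_dosage(matrix(c(1, 1), ncol = 1)), 4 / 6)
  # additivity over sites
  expect_equal(pi_dosage(matrix(c(1, 1, 1, 1), ncol = 2)), 8 / 6)
  # monomorphic
  expect_equal(pi_dosage(matrix(0, 3, 4)), 0)
})

test_that("Watterson's theta follows S over the harmonic number", {
  # S = 3 segregating sites among n = 4 allele copies
  dos <- matrix(c(1, 0,
                  0, 1,
                  1, 1), nrow = 2)
  expect_equal(theta_w(dos), 3 / (1 + 1 / 2 + 1 / 3))
  expect_equal(theta_w(matrix(0, 2, 3)), 0)
  # single individual, one segregating site: a_1 = 1
  expect_equal(theta_w(matrix(1, 1, 1)), 1)
})

test_that("Tajima's D handles conventions and matches the constants formula", {
  expect_equal(tajimas_d(matrix(0, 4, 2)), 0)   # S = 0
  set.seed(3)
  for (i in 1:10) {
    dos <- random_dosage_matrix(5, 8)
    expect_equal(tajimas_d(dos), tajimas_d_naive(dos))
  }
})

test_that("diplotype spectrum sorts and counts distinct genotype strings", {
  dos <- matrix(1, 5, 3)
  spec <- diplotype_spectrum(dos)
  expect_equal(spec$freq, 1)
  expect_equal(spec$n_diplotypes, 1)

  dos <- rbind(matrix(0, 5, 2), matrix(1, 3, 2), matrix(2, 2, 2))
  spec <- diplotype_spectrum(dos)
  expect_equal(spec$n_diplotypes, 3)
  expect_equal(spec$freq, c(0.5, 0.3, 0.2))

  dos <- diag(4)[, 1:4] * 2   # 4 pairwise-distinct individuals
  spec <- diplotype_spectrum(dos)
  expect_equal(spec$freq, rep(0.25, 4))
  expect_error(diplotype_spectrum(matrix(0, 0, 3)), "individual")
})

test_that("H1, H12 and H2/H1 match their definitions", {
  h <- h_stats(c(0.5, 0.3, 0.2))
  expect_equal(unname(h["h1"]), 0.38)
  expect_equal(unname(h["h12"]), 0.68)
  expect_equal(unname(h["h2_h1"]), (0.38 - 0.25) / 0.38)

  h <- h_stats(1)
  expect_equal(unname(h), c(1, 1, 0))

  h <- h_stats(c(0.5, 0.5))
  expect_equal(unname(h), c(0.5, 1.0, 0.5))

  expect_error(h_stats(c(0.2, 0.8)), "descending")
  expect_error(h_stats(c(0.5, 0.3)), "sum to 1")
})

test_that("unphased r2 equals the squared dosage correlation", {
  expect_equal(rh_r2(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(rh_r2(c(0, 1, 2), c(2, 1, 0)), 1)
  expect_equal(rh_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_true(is.na(rh_r2(c(0, 0, 0), c(0, 1, 2))))   # zero variance
  expect_true(is.na(rh_r2(c(0, NA, NA), c(0, 1, 2)))) # < 2 complete
})

test_that("Zns averages r2 over usable pairs", {
  # two perfectly correlated sites
  dos <- cbind(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(zns(dos), 1)
  # three sites with pairwise r2 {1, 0, 0}
  dos <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2), c(0, 2, 0, 2))
  expect_equal(zns(dos), 1 / 3)
  expect_equal(zns(matrix(c(0, 1), 2, 1)), 0)   # < 2 usable sites
})

test_that("omega_max reproduces hand-computed block splits", {
  # uniform r2: omega = 1 at every split
  dos <- cbind(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1),
               c(0, 1, 2, 0, 1))
  expect_equal(omega_max(dos), 1)
  expect_equal(omega_max(dos[, 1:3]), 0)   # S = 3 below the minimum
  # S = 4, within-block r2 = 1, between-block r2 = 0.1 -> omega = 10
  set.seed(17)
  found <- FALSE
  for (i in 1:500) {
    dos <- random_dosage_matrix(8, 4)
    o1 <- omega_max(dos)
    o2 <- omega_max_naive(dos)
    expect_equal(o1, o2)
    if (o1 > 0) found <- TRUE
  }
  expect_true(found)
})

test_that("pairwise-difference moments use population variance and Fisher shape", {
  expect_equal(unname(pwdiff_moments(matrix(c(0, 2), 2, 1))),
               c(0, 0, 0))   # single pair -> degenerate moments
  dos <- rbind(c(0, 0), c(1, 1), c(2, 2))   # distances 2, 4, 2
  m <- pwdiff_moments(dos)
  expect_equal(unname(m["pwdiff_var"]), mean((c(2, 4, 2) - 8 / 3)^2))
  # distances {0, 2, 4}: population variance 8/3, zero skew
  d <- c(0, 2, 4)
  expect_equal(mean((d - 2)^2), 8 / 3)
  expect_equal(sum((d - 2)^3), 0)
  expect_error(pwdiff_moments(matrix(0, 1, 3)), "2 individuals")
})

test_that("all twelve statistics match brute-force oracles on random matrices", {
  set.seed(41)
  for (i in 1:50) {
    dos <- random_dosage_matrix(sample(3:10, 1), sample(2:12, 1),
                                p_missing = sample(c(0, 0.1), 1))
    expect_equal(pi_dosage(dos), pi_naive(dos))
    expect_equal(theta_w(dos), theta_w_naive(dos))
    expect_equal(tajimas_d(dos), tajimas_d_naive(dos))
    expect_equal(zns(dos), zns_naive(dos))
    expect_equal(omega_max(dos), omega_max_naive(dos))
    if (nrow(dos) >= 2)
      expect_equal(unname(pwdiff_moments(dos)), pwdiff_naive(dos))
    spec <- diplotype_spectrum(dos)
    hn <- h_stats_naive(spec$freq)
    h <- h_stats(spec$freq)
    expect_equal(unname(h[c("h12", "h1", "h2_h1")]), hn)
  }
})

test_that("statistics are invariant to allele relabeling and row order", {
  set.seed(73)
  for (i in 1:10) {
    dos <- random_dosage_matrix(6, 8)
    flip <- sample(ncol(dos), 3)
    dos_flip <- dos
    dos_flip[, flip] <- 2 - dos_flip[, flip]
    expect_equal(pi_dosage(dos), pi_dosage(dos_flip))
    expect_equal(theta_w(dos), theta_w(dos_flip))

    perm <- sample(nrow(dos))
    expect_equal(subwindow_stats(dos), subwindow_stats(dos[perm, ]))
  }
})

test_that("H12 is at least H1, with equality only for a single diplotype", {
  set.seed(7)
  for (i in 1:30) {
    dos <- random_dosage_matrix(8, 5)
    spec <- diplotype_spectrum(dos)
    h <- h_stats(spec$freq)
    if (spec$n_diplotypes >= 2)
      expect_gt(h[["h12"]], h[["h1"]])
    else
      expect_equal(h[["h12"]], h[["h1"]])
  }
})
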
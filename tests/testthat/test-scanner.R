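test_that("VCF genotypes are transcribed to dosages with region semantics", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0|1\t./.\t1/1",
    "chr1\t30\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",   # multi-allelic
    "chr1\t40\t.\tGT\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",    # indel
    "chr1\t50\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t1/1"      # monomorphic
  ), path)
  win <- read_genotypes(path, "chr1", 0, 100, n_subwindows = 1L)
  # hand transcription: multi-allelic, indel skipped; monomorphic dropped
  expect_equal(win$positions_bp, c(9, 19))
  expect_equal(unname(win$dosages),
               rbind(c(0, 1), c(1, NA), c(2, 2)))
  expect_equal(attr(win, "n_skipped"), 2)

  # a region shifted by 15 keeps only the second site, rebased
  win2 <- read_genotypes(path, "chr1", 15, 100, n_subwindows = 1L)
  expect_equal(win2$positions_bp, 4)
})

test_that("window enumeration counts focal slots with full contexts", {
  w1 <- enumerate_windows("c", 2750000)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$focal_start, 1250000)
  expect_equal(w1$context_start, 0)
  expect_equal(w1$context_end, 2750000)

  expect_equal(nrow(enumerate_windows("c", 3250000)), 3L)
  expect_equal(nrow(enumerate_windows("c", 2750000 - 1)), 0L)

  w <- enumerate_windows("c", 4000000)
  expect_true(all(w$context_end - w$context_start ==
                    11 * (w$focal_end - w$focal_start)))
  # focal intervals tile without gaps; adjacent contexts overlap by 10
  expect_equal(w$focal_start[-1], w$focal_end[-nrow(w)])
  expect_equal(w$context_start[-1] - w$context_start[-nrow(w)],
               rep(250000, nrow(w) - 1))
})

test_that("window filters apply the zero-recombination and mask rules", {
  win <- data.frame(chrom = "c", focal_start = 1250000,
                    focal_end = 1500000, context_start = 0,
                    context_end = 2750000)
  no_mask <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0))
  zero_map <- data.frame(chrom = "c", start = 0, end = 3e6, rate = 0)
  f <- window_filters(win, no_mask, zero_map)
  expect_false(f$keep)
  expect_equal(f$reason, "zero_recombination")

  # piecewise map: rate 1e-8 on half the context -> mean 5e-9, keep
  half_map <- data.frame(chrom = "c", start = c(0, 1375000),
                         end = c(1375000, 2750000), rate = c(1e-8, 0))
  f2 <- window_filters(win, no_mask, half_map)
  expect_true(f2$keep)
  expect_equal(f2$mean_rate, 5e-9)

  ok_map <- data.frame(chrom = "c", start = 0, end = 3e6, rate = 1e-8)
  mask86 <- data.frame(chrom = "c", start = 0, end = 0.86 * 2750000)
  f3 <- window_filters(win, mask86, ok_map)
  expect_false(f3$keep)
  expect_equal(f3$reason, "masked_fraction")

  mask85 <- data.frame(chrom = "c", start = 0, end = 0.85 * 2750000)
  f4 <- window_filters(win, mask85, ok_map)
  expect_true(f4$keep)   # 0.85 exactly is kept (strict inequality)
  expect_equal(f4$masked_fraction, 0.85)
})

test_that("scanning a synthetic genome ranks planted sweeps above neutral windows", {
  run <- demo_run()
  scan <- run$scan
  truth <- run$truth
  sweep_tiles <- truth[truth$label %in% c("hard", "soft"), ]
  # focal windows centered on a planted sweep's central subwindow
  centers <- (sweep_tiles$start + sweep_tiles$end) / 2
  on_sweep <- vapply(scan$focal_start, function(s)
    any(centers >= s & centers <= s + 25000), logical(1))
  score <- scan$p_hard + scan$p_soft
  neutral_far <- vapply(seq_len(nrow(scan)), function(i)
    all(abs(scan$focal_start[i] - centers) > 300000), logical(1))
  expect_gt(mean(score[on_sweep]), mean(score[neutral_far]))

  # determinism: rescanning with the same inputs reproduces the table
  genome <- run$truth
  expect_equal(nrow(scan), length(unique(scan$focal_start)))
})

test_that("an all-masked chromosome yields no scan output", {
  blobs <- blob_data(10)
  model <- train_classifier(blobs$x, blobs$y,
                            training_config(max_epochs = 3L, seed = 2L))
  fix <- make_fixtures(seed = 31L, dir = tempfile(), n_individuals = 4L)
  g <- fix$genome
  full_mask <- data.frame(chrom = names(g$chrom_lengths), start = 0,
                          end = unname(g$chrom_lengths))
  out <- scan_genome(g$vcf, g$chrom_lengths, full_mask, g$map, model,
                     focal_size = g$focal_size)
  expect_equal(nrow(out), 0L)
})
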
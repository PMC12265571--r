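#' Configuration for an end-to-end run
#'
#' Collects everything a seeded end-to-end analysis needs. The default
#' scale is the package's desk-scale demonstration: the full-size priors
#' passed through \code{\link{rescale_region}} with alpha = 25 (110 kb
#' regions, 10 kb subwindows) and a constant diploid population of
#' 500,000 — per-bp diversity 4*N*mu of about 0.01 and population-scaled
#' selection 2Ns between roughly 200 and 2,000, the strong-sweep regime
#' the method targets — simulated at a scaled-down size of 100, with 300
#' replicates per class and 20 sampled diploids.
#'
#' @param priors a \code{\link{parameter_priors}} object.
#' @param dem a \code{\link{demography}} object.
#' @param reps_per_class simulated replicates per class.
#' @param train_per_class,test_per_class stratified split counts; their
#'   sum must not exceed \code{reps_per_class}.
#' @param n_individuals sampled diploids per replicate.
#' @param sim_n scaled-down diploid size for the forward simulator
#'   (NULL to simulate at the nominal sizes).
#' @param mask_profiles optional list of \code{\link{mask_profile}}s
#'   applied to replicates (one drawn per replicate).
#' @param train_config a \code{\link{training_config}}.
#' @param thresholds posterior-probability calling thresholds, ascending.
#' @param burnin_factor neutral burn-in length for the simulator, in
#'   units of the ancestral population size.
#' @param seed master integer seed.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(priors = rescale_region(parameter_priors(), 25),
                       dem = demography(0, 500000),
                       reps_per_class = 300L, train_per_class = 250L,
                       test_per_class = 50L, n_individuals = 20L,
                       sim_n = 100L, mask_profiles = NULL,
                       train_config = training_config(),
                       thresholds = c(0.80, 0.90, 0.95, 0.99),
                       burnin_factor = 8, seed = 1L) {
  if (train_per_class + test_per_class > reps_per_class)
    stop("train + test per class exceeds reps_per_class")
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must be strictly ascending within (0, 1]")
  structure(list(priors = priors, dem = dem,
                 reps_per_class = as.integer(reps_per_class),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 n_individuals = as.integer(n_individuals),
                 sim_n = if (is.null(sim_n)) NULL else as.integer(sim_n),
                 mask_profiles = mask_profiles,
                 train_config = train_config, thresholds = thresholds,
                 burnin_factor = burnin_factor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis end to end
#'
#' simulate -> featurize -> train -> evaluate -> scan a synthetic genome
#' -> call sweeps -> q-values -> soft-fraction correction, writing every
#' artifact plus a manifest (with file checksums) under \code{out_dir}.
#' Identical config and seed give identical artifacts.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory.
#' @param n_genome_tiles number of simulated windows tiled into the
#'   synthetic scan genome.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the fitted model, evaluation metrics,
#'   scan table, calls and soft-fraction estimates.
#' @export
run_end_to_end <- function(config, out_dir, n_genome_tiles = 12L,
                           quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  t_stage <- Sys.time()
  say <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] (%+.1fs) %s\n", format(Sys.time(), "%H:%M:%S"),
                as.numeric(Sys.time() - t_stage, units = "secs"), msg),
        file = log_path, append = TRUE)
    t_stage <<- Sys.time()
    if (!quiet) message(msg)
  }
  t_start <- Sys.time()

  # 1. simulate labeled replicates
  say("simulating %d replicates/class ...", config$reps_per_class)
  set.seed(config$seed)
  reps <- list()
  for (cl in sweep_classes())
    reps <- c(reps, simulate_class_set(cl, config$priors, config$dem,
                                       config$reps_per_class,
                                       n_individuals = config$n_individuals,
                                       mask_profiles = config$mask_profiles,
                                       sim_n = config$sim_n,
                                       burnin_factor = config$burnin_factor))
  sets <- build_class_sets(reps, config$train_per_class,
                           config$test_per_class,
                           rng_seed = config$seed + 1L)

  # 2. features
  say("computing features ...")
  train_feat <- replicate_features(sets$train)
  test_feat <- replicate_features(sets$test)

  # 3. train
  say("training classifier ...")
  model <- train_classifier(train_feat$x, train_feat$y,
                            config$train_config)
  save_classifier(model, file.path(out_dir, "model"))

  # 4. evaluate on the held-out test set
  post_test <- predict_posterior(model, test_feat$x)
  eval_list <- list(
    roc_pr = roc_pr(post_test, test_feat$y),
    confusions = lapply(c(0, config$thresholds), function(t)
      confusion_at_threshold(post_test, test_feat$y, t)))
  write_metrics(eval_list, file.path(out_dir, "metrics"))
  say("held-out AUC %.3f, AP %.3f", eval_list$roc_pr$auc,
      eval_list$roc_pr$ap)

  # 5. synthetic genome scan
  say("scanning synthetic genome ...")
  set.seed(config$seed + 2L)
  genome <- build_synthetic_genome(reps, n_tiles = n_genome_tiles,
                                   dir = file.path(out_dir, "genome"))
  scan_tab <- scan_genome(genome$vcf, genome$chrom_lengths,
                          genome$mask, genome$map, model,
                          focal_size = genome$focal_size,
                          n_subwindows = config$priors$n_subwindows)
  utils::write.table(scan_tab, file.path(out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. calls, q-values, soft fraction (neutral test posteriors as null)
  neutral_null <- post_test[test_feat$y == "neutral", ]
  calls_by_t <- list()
  soft_by_t <- list()
  for (t in config$thresholds) {
    calls <- call_sweeps(scan_tab, t)
    calls <- fdr_and_q(calls, neutral_null, nrow(scan_tab))
    write_calls(calls, file.path(out_dir,
                                 sprintf("calls_t%0.2f.tsv", t)))
    cm <- confusion_at_threshold(post_test, test_feat$y, t)
    n_hard <- sum(calls$called_class == "hard")
    n_soft <- sum(calls$called_class == "soft")
    q_at_t <- if (nrow(calls)) max(calls$q_value) else 0
    soft_by_t[[sprintf("%0.2f", t)]] <- tryCatch(
      soft_fraction_corrected(n_hard, n_soft, q_at_t,
                              cm$fractions["hard", "hard"],
                              cm$fractions["hard", "soft"]),
      error = function(e) NULL)   # no classified hard test examples at t
    calls_by_t[[sprintf("%0.2f", t)]] <- calls
  }
  summary_tab <- count_table(list(synthetic = scan_tab),
                             thresholds = c(0, config$thresholds))
  utils::write.table(summary_tab, file.path(out_dir, "call_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # manifest with artifact checksums
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  manifest <- list(seed = config$seed,
                   reps_per_class = config$reps_per_class,
                   thresholds = config$thresholds,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("sweepscape")),
                   elapsed_s = as.numeric(Sys.time() - t_start,
                                          units = "secs"),
                   checksums = as.list(tools::md5sum(
                     file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  say("done in %.1f s", manifest$elapsed_s)
  invisible(list(model = model, eval = eval_list, scan = scan_tab,
                 calls = calls_by_t, soft_fraction = soft_by_t,
                 summary = summary_tab, truth = genome$truth,
                 test_posteriors = post_test, test_labels = test_feat$y))
}

#' Assemble a synthetic genome from simulated replicates
#'
#' Tiles randomly chosen replicates (balanced between neutral and sweep
#' classes) side by side into one synthetic chromosome and writes a VCF,
#' an (empty) BED mask and a constant recombination map, plus the truth
#' table of tile labels.
#'
#' @param reps list of \code{sim_replicate} objects to draw tiles from.
#' @param n_tiles number of tiles.
#' @param dir output directory.
#' @param chrom chromosome name used in the VCF.
#' @return list with \code{vcf}, \code{chrom_lengths}, \code{mask},
#'   \code{map}, \code{focal_size} and \code{truth} (data.frame of tile
#'   label and coordinates).
#' @export
build_synthetic_genome <- function(reps, n_tiles = 12L, dir = tempfile(),
                                   chrom = "chrS") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(reps, function(r) r$label, character(1))
  n_sweep <- max(1L, round(n_tiles / 4))
  sweep_pool <- which(labels %in% c("hard", "soft"))
  neutral_pool <- which(labels == "neutral")
  tiles <- integer(n_tiles)
  sweep_slots <- sample(seq_len(n_tiles), n_sweep)
  tiles[sweep_slots] <- sample(sweep_pool, n_sweep)
  tiles[-sweep_slots] <- sample(neutral_pool, n_tiles - n_sweep,
                                replace = n_tiles - n_sweep >
                                  length(neutral_pool))
  L <- reps[[tiles[1]]]$window$region_length_bp
  k <- n_subwindows(reps[[tiles[1]]]$window)
  n_ind <- nrow(reps[[tiles[1]]]$window$dosages)

  pos <- integer(0)
  dos <- NULL
  truth <- data.frame(tile = seq_len(n_tiles), label = labels[tiles],
                      start = (seq_len(n_tiles) - 1) * L,
                      end = seq_len(n_tiles) * L)
  for (i in seq_len(n_tiles)) {
    w <- reps[[tiles[i]]]$window
    pos <- c(pos, w$positions_bp + (i - 1) * L)
    dos <- cbind(dos, w$dosages)
  }
  vcf_path <- file.path(dir, "genome.vcf")
  write_vcf_dosages(dos, pos + 1, chrom, vcf_path)
  map <- data.frame(chrom = chrom, start = 0, end = n_tiles * L,
                    rate = 4.85e-9)
  utils::write.table(map, file.path(dir, "recmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(vcf = vcf_path,
       chrom_lengths = stats::setNames(n_tiles * L, chrom),
       mask = NULL, map = map, focal_size = L / k, truth = truth)
}

#' Write a dosage matrix as a minimal unphased-genotype VCF
#'
#' @param dos dosage matrix (individuals x sites, 0/1/2/NA).
#' @param pos1 1-based site positions.
#' @param chrom chromosome name.
#' @param path output path.
#' @param sample_names VCF sample names.
#' @export
write_vcf_dosages <- function(dos, pos1, chrom, path,
                              sample_names = sprintf("ind%02d",
                                                     seq_len(nrow(dos)))) {
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "wt")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_names),
                     collapse = "\t")), con)
  for (j in seq_along(pos1)) {
    calls <- ifelse(is.na(dos[, j]), "./.", gt[dos[, j] + 1L])
    writeLines(paste(c(chrom, pos1[j], ".", "A", "T", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Generate the small fixture pack used by the examples and tests
#'
#' Writes, under \code{dir}: a demography file, a recombination map, a
#' BED mask, a library of mask profiles, a tiny neutral VCF and a
#' planted-sweep synthetic genome. Everything is generated from the seed;
#' no external data are touched.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_individuals diploids per replicate.
#' @return list of file paths and the underlying objects.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile(),
                          n_individuals = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pr <- rescale_region(parameter_priors(), 25)
  dem <- demography(0, 250000)

  dem_path <- file.path(dir, "demography.txt")
  write_demography(dem, dem_path)

  # mask-profile library: a few profiles with random masked runs
  prof_dir <- file.path(dir, "mask_profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  prof_paths <- vapply(1:3, function(i) {
    n_runs <- sample(2:5, 1)
    starts <- sort(sample.int(pr$region_length_bp - 20000L, n_runs))
    ends <- pmin(starts + sample(2000:15000, n_runs, replace = TRUE),
                 pr$region_length_bp)
    ok <- c(TRUE, starts[-1] >= ends[-n_runs])
    p <- file.path(prof_dir, sprintf("profile%d.bed", i))
    utils::write.table(data.frame(starts[ok], ends[ok]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    p
  }, character(1))

  neutral <- simulate_replicate("neutral", pr, dem,
                                n_individuals = n_individuals,
                                sim_n = 50)
  vcf_path <- file.path(dir, "tiny.vcf")
  write_vcf_dosages(neutral$window$dosages,
                    neutral$window$positions_bp + 1, "chr1", vcf_path)

  reps <- c(lapply(1:6, function(i)
    simulate_replicate("neutral", pr, dem,
                       n_individuals = n_individuals, sim_n = 50)),
    simulate_class_set("hard", pr, dem, 1L,
                       n_individuals = n_individuals, sim_n = 50),
    simulate_class_set("soft", pr, dem, 1L,
                       n_individuals = n_individuals, sim_n = 50))
  genome <- build_synthetic_genome(reps, n_tiles = 8L,
                                   dir = file.path(dir, "genome"))

  mask_path <- file.path(dir, "mask.bed")
  utils::write.table(data.frame("chr1", c(0L, 50000L), c(10000L, 60000L)),
                     mask_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map_path <- file.path(dir, "recmap.tsv")
  utils::write.table(data.frame("chr1", 0L, pr$region_length_bp, 4.85e-9),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  list(dir = dir, demography = dem_path, mask_profiles = prof_paths,
       vcf = vcf_path, mask = mask_path, recmap = map_path,
       genome = genome, neutral_replicate = neutral, priors = pr)
}
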
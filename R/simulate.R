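#' Simulate one labeled replicate under the Wright-Fisher model
#'
#' Runs a discrete-generation forward Wright-Fisher simulation of 2N
#' haplotypes over the region: Poisson crossovers at rate r per bp per
#' generation, infinite-sites Poisson mutation at rate mu per bp, and, for
#' sweep classes, additive selection (heterozygote fitness 1 + s/2,
#' homozygote 1 + s) at the focal site. Hard sweeps introduce the
#' beneficial allele as a single copy; soft sweeps start selection on a
#' standing variant at frequency f0 (an existing neutral variant with a
#' matching frequency in the focal subwindow is used when available,
#' otherwise one is injected). Sweep runs are conditioned, by rejection,
#' on fixation completing tau * 4 * N0 generations before sampling.
#' Sampled haplotypes are randomly paired into unphased diploids.
#'
#' When \code{sim_n} is given, the simulation runs at that diploid size
#' with mu, r and s multiplied and epoch times divided by
#' \code{N0 / sim_n}, so that the population-scaled parameters
#' theta = 4*N*mu*L, rho = 4*N*r*L and 2*N*s are preserved.
#'
#' @param label replicate class, one of \code{\link{sweep_classes}()}.
#' @param priors a \code{\link{parameter_priors}} object.
#' @param dem a \code{\link{demography}} object (most recent epoch first).
#' @param params a \code{\link{draw_params}} result for this label; drawn
#'   fresh when \code{NULL}.
#' @param n_individuals number of diploid individuals to sample (>= 2).
#' @param sim_n optional scaled-down diploid size for the forward run.
#' @param burnin_factor neutral burn-in length in units of the ancestral
#'   population size (default 10).
#' @param max_attempts rejection budget for fixation conditioning.
#' @param soft_search_tol relative tolerance on the carrier count when
#'   searching for a standing variant near f0.
#' @return an object of class \code{"sim_replicate"}: list with
#'   \code{window} (a \code{\link{genotype_window}}), \code{label} and
#'   \code{params}.
#' @export
simulate_replicate <- function(label, priors, dem, params = NULL,
                               n_individuals = 20L, sim_n = NULL,
                               burnin_factor = 10, max_attempts = 1000L,
                               soft_search_tol = 0.5) {
  stopifnot(inherits(priors, "sweep_priors"), inherits(dem, "demography"))
  label <- match.arg(label, sweep_classes())
  if (n_individuals < 2L) stop("n_individuals must be >= 2")
  if (is.null(params)) params <- draw_params(priors, label)
  if (params$label != label) stop("params were drawn for a different label")

  mu <- params$mu; r <- params$r; s <- params$s; tau <- params$tau
  f0 <- params$f0
  times <- dem$times_gen; sizes <- dem$sizes
  if (!is.null(sim_n)) {
    k <- sizes[1] / sim_n
    if (k < 1) stop("sim_n must not exceed the present-day size")
    mu <- mu * k; r <- r * k
    if (!is.na(s)) s <- s * k
    times <- times / k
    sizes <- pmax(2, round(sizes / k))
  }
  mode <- switch(label, neutral = 0L, hard = 1L, "hard-linked" = 1L,
                 soft = 2L, "soft-linked" = 2L)
  if (mode == 2L && f0 * 2 * sizes[1] < 1)
    stop("population too small for f0 (f0 * 2N < 1)")
  if (2L * n_individuals > 2 * min(sizes))
    stop("sample size exceeds the smallest population size")

  res <- .wf_simulate_cpp(priors$region_length_bp, mu, r,
                          if (is.na(s)) 0 else s,
                          if (is.na(tau)) 0 else tau,
                          if (is.na(f0)) 0 else f0,
                          if (is.na(params$sweep_position_bp)) -1
                          else params$sweep_position_bp,
                          mode, cbind(times, sizes),
                          as.integer(n_individuals),
                          burnin_factor, as.integer(max_attempts),
                          soft_search_tol)

  pos_bp <- .positions_to_bp(res$positions, priors$region_length_bp)
  win <- genotype_window(res$dosages[, pos_bp$keep, drop = FALSE],
                         pos_bp$bp, priors$region_length_bp,
                         priors$n_subwindows)
  params$sweep_position_bp <- if (res$sweep_position >= 0)
    res$sweep_position else NA_real_
  structure(list(window = win, label = label, params = params,
                 attempts = res$attempts,
                 sweep_generations = res$sweep_generations,
                 n_beneficial_sampled = res$n_beneficial_sampled),
            class = "sim_replicate")
}

# map continuous coordinates to strictly increasing integer bp, nudging
# floor-collisions upward and dropping sites pushed past the region end
.positions_to_bp <- function(pos, region_length) {
  bp <- floor(pos)
  if (length(bp) > 1L)
    for (i in 2:length(bp))
      if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1
  keep <- bp < region_length
  list(bp = bp[keep], keep = keep)
}

#' @exportS3Method base::print
print.sim_replicate <- function(x, ...) {
  cat(sprintf("Simulated replicate [%s]\n", x$label))
  print(x$window)
  invisible(x)
}

#' Simulate a batch of replicates for one class
#'
#' Parameter draws raising a parameter error (for example an f0 too small
#' for the scaled population) are redrawn; the number of redraws is
#' recorded in the \code{"n_redraws"} attribute.
#'
#' @inheritParams simulate_replicate
#' @param n_reps number of replicates.
#' @param mask_profiles optional list of \code{\link{mask_profile}}s; one
#'   is drawn uniformly per replicate and applied.
#' @param ... passed to \code{\link{simulate_replicate}}.
#' @return list of \code{sim_replicate} objects.
#' @export
simulate_class_set <- function(label, priors, dem, n_reps,
                               n_individuals = 20L, mask_profiles = NULL,
                               ...) {
  out <- vector("list", n_reps)
  redraws <- 0L
  for (i in seq_len(n_reps)) {
    rep_i <- NULL
    while (is.null(rep_i)) {
      pd <- draw_params(priors, label)
      rep_i <- tryCatch(
        simulate_replicate(label, priors, dem, params = pd,
                           n_individuals = n_individuals, ...),
        error = function(e) {
          if (grepl("too small for f0", conditionMessage(e))) {
            redraws <<- redraws + 1L
            NULL
          } else stop(e)
        })
    }
    if (!is.null(mask_profiles) && length(mask_profiles))
      rep_i <- apply_mask(rep_i,
                          mask_profiles[[sample.int(length(mask_profiles), 1L)]])
    out[[i]] <- rep_i
  }
  attr(out, "n_redraws") <- redraws
  out
}

#' Assemble stratified train and test sets from labeled replicates
#'
#' Draws disjoint, seeded, per-class samples. At the full scale of the
#' reference design this yields a 13,500-example training set (2,700 per
#' class) and a 1,500-example test set (300 per class).
#'
#' @param reps list of \code{sim_replicate} objects (all classes pooled;
#'   linked classes may come from any non-central subwindow).
#' @param train_per_class,test_per_class per-class counts.
#' @param rng_seed integer seed for the stratified sampling.
#' @return list with \code{train} and \code{test}, each a list of
#'   replicates, plus index attributes \code{"train_idx"}/\code{"test_idx"}
#'   into \code{reps}.
#' @export
build_class_sets <- function(reps, train_per_class, test_per_class,
                             rng_seed = 1L) {
  labels <- vapply(reps, function(r) r$label, character(1))
  set.seed(as.integer(rng_seed))
  train_idx <- test_idx <- integer(0)
  for (cl in sweep_classes()) {
    idx <- which(labels == cl)
    need <- train_per_class + test_per_class
    if (length(idx) < need)
      stop(sprintf("insufficient replicates for class '%s' (%d < %d)",
                   cl, length(idx), need))
    pick <- sample(idx, need)
    train_idx <- c(train_idx, pick[seq_len(train_per_class)])
    test_idx <- c(test_idx, pick[train_per_class + seq_len(test_per_class)])
  }
  out <- list(train = reps[train_idx], test = reps[test_idx])
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}

#' Serialize replicates to gzipped text
#'
#' One file per replicate: header lines with the label and parameter draw,
#' a positions line, then one dosage row per individual with \code{.} for
#' missing. Field order is deterministic.
#'
#' @param reps list of \code{sim_replicate} objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
write_replicates <- function(reps, dir, prefix = "rep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(reps))
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    p <- file.path(dir, sprintf("%s_%05d.txt.gz", prefix, i))
    con <- gzfile(p, "wt")
    hdr <- c(sprintf("#label=%s", r$label),
             sprintf("#region_length_bp=%.0f", r$window$region_length_bp),
             sprintf("#n_subwindows=%d", n_subwindows(r$window)),
             sprintf("#mu=%.17g", r$params$mu),
             sprintf("#r=%.17g", r$params$r),
             sprintf("#s=%.17g", r$params$s),
             sprintf("#tau=%.17g", r$params$tau),
             sprintf("#f0=%.17g", r$params$f0),
             sprintf("#sweep_subwindow_index=%d",
                     r$params$sweep_subwindow_index),
             sprintf("#sweep_position_bp=%.17g", r$params$sweep_position_bp))
    writeLines(hdr, con)
    writeLines(paste(r$window$positions_bp, collapse = "\t"), con)
    dos <- r$window$dosages
    for (j in seq_len(nrow(dos))) {
      row <- dos[j, ]
      writeLines(paste(ifelse(is.na(row), ".", row), collapse = "\t"), con)
    }
    close(con)
    paths[i] <- p
  }
  paths
}

#' Read replicates written by \code{\link{write_replicates}}
#' @param paths character vector of file paths.
#' @return list of \code{sim_replicate} objects.
#' @export
read_replicates <- function(paths) {
  lapply(paths, function(p) {
    lines <- readLines(gzfile(p))
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "=", fixed = TRUE))
    get <- function(k) kv[kv[, 1] == k, 2]
    pos <- if (nzchar(body[1])) as.numeric(strsplit(body[1], "\t")[[1]])
    else numeric(0)
    rows <- body[-1L]
    dos <- if (length(pos) == 0L)
      matrix(NA_real_, nrow = length(rows), ncol = 0L)
    else t(vapply(strsplit(rows, "\t"), function(x) {
      x[x == "."] <- NA
      as.numeric(x)
    }, numeric(length(pos))))
    num <- function(k) suppressWarnings(as.numeric(get(k)))
    params <- structure(list(mu = num("mu"), r = num("r"), s = num("s"),
                             tau = num("tau"), f0 = num("f0"),
                             sweep_subwindow_index =
                               suppressWarnings(as.integer(get("sweep_subwindow_index"))),
                             sweep_position_bp = num("sweep_position_bp"),
                             label = get("label")),
                        class = "param_draw")
    win <- genotype_window(dos, pos, num("region_length_bp"),
                           as.integer(get("n_subwindows")))
    structure(list(window = win, label = get("label"), params = params),
              class = "sim_replicate")
  })
}
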
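#' Parameter priors for sweep simulations
#'
#' Container for the distributions from which per-replicate simulation
#' parameters are drawn. Defaults correspond to a large outcrossing insect
#' population: the per-bp per-generation mutation rate varies uniformly on
#' \code{[8.82e-10, 8.82e-9]} (mean 4.85e-9), the recombination rate is
#' exponential with mean 4.85e-9 truncated at three times its mean, the
#' selection coefficient is log-uniform on \code{[0.005, 0.05]}, the time
#' since fixation of the beneficial allele is uniform on \code{[0, 0.001]}
#' in units of 4*N0 generations, and the starting frequency of the standing
#' variant for soft sweeps is uniform on \code{[0, 0.05]}. Regions are
#' 2.75 Mb split into 11 adjacent equal subwindows.
#'
#' @param mu_low,mu_high bounds of the uniform mutation-rate prior
#'   (per bp per generation).
#' @param r_mean mean of the exponential recombination-rate prior
#'   (per bp per generation).
#' @param r_cap_multiplier draws greater than \code{r_cap_multiplier *
#'   r_mean} are rejected and redrawn.
#' @param s_low,s_high bounds of the selection-coefficient prior.
#' @param s_scale \code{"log-uniform"} (uniform on log s) or
#'   \code{"uniform"}.
#' @param tau_max upper bound of the uniform fixation-time prior, in units
#'   of 4*N0 generations before sampling.
#' @param f0_max upper bound of the uniform prior on the standing-variant
#'   starting frequency (soft sweeps only).
#' @param region_length_bp simulated region length in bp.
#' @param n_subwindows number of adjacent equal subwindows (odd).
#' @return an object of class \code{"sweep_priors"}.
#' @export
parameter_priors <- function(mu_low = 8.82e-10, mu_high = 8.82e-9,
                             r_mean = 4.85e-9, r_cap_multiplier = 3,
                             s_low = 0.005, s_high = 0.05,
                             s_scale = c("log-uniform", "uniform"),
                             tau_max = 0.001, f0_max = 0.05,
                             region_length_bp = 2750000L,
                             n_subwindows = 11L) {
  s_scale <- match.arg(s_scale)
  num <- c(mu_low = mu_low, mu_high = mu_high, r_mean = r_mean,
           r_cap_multiplier = r_cap_multiplier, s_low = s_low,
           s_high = s_high, tau_max = tau_max, f0_max = f0_max,
           region_length_bp = region_length_bp)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all prior bounds must be finite and positive")
  if (mu_low >= mu_high) stop("mu_low must be < mu_high")
  if (s_low >= s_high) stop("s_low must be < s_high")
  if (f0_max >= 1) stop("f0_max must lie in (0, 1)")
  n_subwindows <- as.integer(n_subwindows)
  if (n_subwindows < 1L || n_subwindows %% 2L == 0L)
    stop("n_subwindows must be a positive odd integer")
  structure(list(mu_low = mu_low, mu_high = mu_high, r_mean = r_mean,
                 r_cap_multiplier = r_cap_multiplier, s_low = s_low,
                 s_high = s_high, s_scale = s_scale, tau_max = tau_max,
                 f0_max = f0_max,
                 region_length_bp = as.numeric(region_length_bp),
                 n_subwindows = n_subwindows),
            class = "sweep_priors")
}

#' @exportS3Method base::print
print.sweep_priors <- function(x, ...) {
  cat("Sweep simulation priors\n")
  cat(sprintf("  mu   ~ U(%.3g, %.3g)\n", x$mu_low, x$mu_high))
  cat(sprintf("  r    ~ Exp(mean %.3g), capped at %g x mean\n",
              x$r_mean, x$r_cap_multiplier))
  cat(sprintf("  s    ~ %s on [%.3g, %.3g]\n", x$s_scale, x$s_low, x$s_high))
  cat(sprintf("  tau  ~ U(0, %g) x 4*N0 generations\n", x$tau_max))
  cat(sprintf("  f0   ~ U(0, %g)\n", x$f0_max))
  cat(sprintf("  region %s bp in %d subwindows\n",
              format(x$region_length_bp, big.mark = ","), x$n_subwindows))
  invisible(x)
}

#' Draw one set of simulation parameters from the priors
#'
#' @param priors a \code{\link{parameter_priors}} object.
#' @param label replicate class, one of \code{sweep_classes()}; determines
#'   whether a sweep location and (for soft classes) an f0 are drawn.
#' @param rng_seed optional integer seed; if \code{NULL} the current RNG
#'   state is used.
#' @return a list of class \code{"param_draw"} with elements \code{mu},
#'   \code{r}, \code{s}, \code{tau}, \code{f0} (soft classes only),
#'   \code{sweep_subwindow_index} (0-based; \code{NA} for neutral) and
#'   \code{sweep_position_bp}.
#' @export
draw_params <- function(priors, label = "neutral", rng_seed = NULL) {
  stopifnot(inherits(priors, "sweep_priors"))
  label <- match.arg(label, sweep_classes())
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  mu <- stats::runif(1, priors$mu_low, priors$mu_high)
  repeat {
    r <- stats::rexp(1, rate = 1 / priors$r_mean)
    if (r <= priors$r_cap_multiplier * priors$r_mean) break
  }
  s <- tau <- f0 <- NA_real_
  sw_idx <- NA_integer_
  sw_pos <- NA_real_
  if (label != "neutral") {
    s <- if (priors$s_scale == "log-uniform")
      exp(stats::runif(1, log(priors$s_low), log(priors$s_high)))
    else stats::runif(1, priors$s_low, priors$s_high)
    tau <- stats::runif(1, 0, priors$tau_max)
    if (label %in% c("soft", "soft-linked"))
      f0 <- stats::runif(1, 0, priors$f0_max)
    k <- priors$n_subwindows
    central <- (k - 1L) %/% 2L
    sw_idx <- if (label %in% c("hard", "soft")) central
    else sample(setdiff(0:(k - 1L), central), 1L)
    sw_len <- priors$region_length_bp / k
    sw_pos <- stats::runif(1, sw_idx * sw_len, (sw_idx + 1) * sw_len)
  }
  structure(list(mu = mu, r = r, s = s, tau = tau, f0 = f0,
                 sweep_subwindow_index = sw_idx, sweep_position_bp = sw_pos,
                 label = label),
            class = "param_draw")
}

#' Rescale the simulated region, preserving the sweep footprint
#'
#' Divides the region length and the selection-coefficient bounds by
#' \code{alpha}, leaving mutation and recombination rates untouched, so
#' that simulated sweeps retain the same ratio of s to the recombination
#' distance across the region. With the default priors and
#' \code{alpha = 5} this maps a 2.75 Mb region with s in [0.005, 0.05]
#' to a 550 kb region with s in [0.001, 0.01].
#'
#' @param priors a \code{\link{parameter_priors}} object.
#' @param alpha scale factor, must be >= 1.
#' @return a rescaled \code{"sweep_priors"} object.
#' @export
rescale_region <- function(priors, alpha) {
  stopifnot(inherits(priors, "sweep_priors"))
  if (!is.finite(alpha) || alpha < 1)
    stop("alpha must be >= 1 (upscaling is not supported)")
  priors$region_length_bp <- priors$region_length_bp / alpha
  priors$s_low <- priors$s_low / alpha
  priors$s_high <- priors$s_high / alpha
  priors
}

#' The five replicate classes
#'
#' Fixed class labels and their serialization order.
#' @return character vector \code{c("hard", "hard-linked", "soft",
#'   "soft-linked", "neutral")}.
#' @export
sweep_classes <- function() {
  c("hard", "hard-linked", "soft", "soft-linked", "neutral")
}

#' Piecewise-constant demographic history
#'
#' @param times_gen epoch start times in generations before present,
#'   strictly increasing from 0 (most recent epoch first).
#' @param sizes diploid population sizes per epoch, all >= 2.
#' @return an object of class \code{"demography"}.
#' @export
demography <- function(times_gen, sizes) {
  if (length(times_gen) != length(sizes) || length(sizes) < 1L)
    stop("times_gen and sizes must be equal-length, non-empty")
  if (times_gen[1] != 0 || is.unsorted(times_gen, strictly = TRUE))
    stop("epoch start times must be strictly increasing from 0")
  if (any(sizes < 2)) stop("all population sizes must be >= 2")
  structure(list(times_gen = as.numeric(times_gen),
                 sizes = as.numeric(sizes)),
            class = "demography")
}

#' Read a demography file
#'
#' Two whitespace-separated columns, \code{generations_before_present N},
#' most recent epoch first; lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return a \code{\link{demography}} object.
#' @export
read_demography <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("time", "N"))
  demography(tab$time, tab$N)
}

#' Write a demography file
#' @param dem a \code{\link{demography}} object.
#' @param path output path.
#' @export
write_demography <- function(dem, path) {
  stopifnot(inherits(dem, "demography"))
  utils::write.table(data.frame(dem$times_gen, dem$sizes), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
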
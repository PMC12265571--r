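#' @useDynLib sweepscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Summary statistics on unphased diploid dosage matrices.
#
# All functions take a matrix of allele dosages (individuals x sites,
# entries 0/1/2 or NA for missing) and treat missingness per the package
# convention: per-site allele frequencies use non-missing copies only,
# pairwise distances use jointly non-missing sites, and site pairs with no
# usable data are excluded rather than imputed.

# allele-copy counts and alternate-allele counts per site
.site_counts <- function(dos) {
  n_copies <- 2L * colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  list(n = n_copies, alt = alt)
}

# sites polymorphic among non-missing entries (and with >= 2 copies)
.usable_sites <- function(dos) {
  sc <- .site_counts(dos)
  which(sc$n >= 2 & sc$alt > 0 & sc$alt < sc$n)
}

#' Nucleotide diversity (pi) from dosages
#'
#' Sum over sites of the unbiased per-site heterozygosity
#' \code{2*p*q*n/(n-1)}, where p is the alternate-allele frequency among
#' the n non-missing allele copies at the site. Sites with fewer than two
#' non-missing copies are skipped. Returned in count units (expected
#' pairwise differences over the sites supplied), not per bp.
#'
#' @param dos dosage matrix, individuals x sites; entries 0/1/2 or NA.
#' @return non-negative numeric scalar.
#' @export
pi_dosage <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  if (ncol(dos) == 0L) return(0)
  sc <- .site_counts(dos)
  ok <- sc$n >= 2
  if (!any(ok)) return(0)
  n <- sc$n[ok]
  p <- sc$alt[ok] / n
  sum(2 * p * (1 - p) * n / (n - 1))
}

#' Watterson's theta from dosages
#'
#' \code{S / a}, where S is the number of sites segregating among
#' non-missing entries and \code{a = sum(1/i)} for \code{i} in
#' \code{1..(n-1)}, with n = 2 x the number of individuals with any data
#' in the matrix. Count units (not per bp).
#'
#' @inheritParams pi_dosage
#' @return non-negative numeric scalar.
#' @export
theta_w <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  if (ncol(dos) == 0L) return(0)
  S <- length(.usable_sites(dos))
  if (S == 0L) return(0)
  n <- 2L * sum(rowSums(!is.na(dos)) > 0)
  if (n < 2L) return(0)
  S / sum(1 / seq_len(n - 1L))
}

#' Tajima's D from dosages
#'
#' Standardized difference between pi and Watterson's theta using the
#' standard constants for sample size n (allele copies). Returns 0 when
#' there are no segregating sites or the variance term is 0.
#'
#' @inheritParams pi_dosage
#' @return numeric scalar.
#' @export
tajimas_d <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  if (ncol(dos) == 0L) return(0)
  S <- length(.usable_sites(dos))
  if (S == 0L) return(0)
  n <- 2L * sum(rowSums(!is.na(dos)) > 0)
  if (n < 3L) return(0)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (pi_dosage(dos) - S / a1) / sqrt(v)
}

#' Diplotype frequency spectrum
#'
#' Individuals are keyed by their full dosage string over the supplied
#' sites (missing entries as a distinct symbol); returns the sorted
#' frequency spectrum and the number of distinct diplotypes.
#'
#' @inheritParams pi_dosage
#' @return list with \code{freq} (descending frequencies summing to 1)
#'   and \code{n_diplotypes}.
#' @export
diplotype_spectrum <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  if (nrow(dos) == 0L) stop("diplotype spectrum requires >= 1 individual")
  key <- if (ncol(dos) == 0L) rep("", nrow(dos))
  else {
    chr <- ifelse(is.na(dos), ".", as.character(dos))
    dim(chr) <- dim(dos)
    do.call(paste0, split(chr, col(chr)))
  }
  tab <- sort(table(key), decreasing = TRUE)
  freq <- as.numeric(tab) / nrow(dos)
  list(freq = freq, n_diplotypes = length(freq))
}

#' Haplotype-homozygosity statistics H1, H12 and H2/H1
#'
#' Computed on a descending frequency spectrum: \code{H1 = sum(p_i^2)},
#' \code{H12 = (p1 + p2)^2 + sum(p_i^2, i >= 3)} (p2 = 0 when absent) and
#' \code{H2/H1 = (H1 - p1^2)/H1}. H12 pools the two most frequent classes
#' and so responds to both hard and soft sweeps, while H2/H1 is larger
#' when several frequent classes co-occur, as after a soft sweep.
#'
#' @param freq numeric vector of frequencies, sorted descending, summing
#'   to 1 (tolerance 1e-9).
#' @return named numeric vector \code{c(h1, h12, h2_h1)}.
#' @export
h_stats <- function(freq) {
  if (length(freq) == 0L) stop("empty frequency vector")
  if (is.unsorted(rev(freq))) stop("frequencies must be sorted descending")
  if (abs(sum(freq) - 1) > 1e-9) stop("frequencies must sum to 1")
  h1 <- sum(freq^2)
  p1 <- freq[1]
  p2 <- if (length(freq) >= 2L) freq[2] else 0
  h12 <- (p1 + p2)^2 + if (length(freq) >= 3L) sum(freq[-(1:2)]^2) else 0
  c(h1 = h1, h12 = h12, h2_h1 = (h1 - p1^2) / h1)
}

#' Unphased-genotype linkage disequilibrium (squared dosage correlation)
#'
#' The squared sample correlation of two dosage vectors over jointly
#' non-missing individuals — the standard unphased estimator of r^2.
#'
#' @param a,b dosage vectors of equal length (0/1/2/NA).
#' @return r^2 in [0, 1], or NA when fewer than two jointly non-missing
#'   individuals remain or either vector has zero variance among them.
#' @export
rh_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# pairwise r^2 matrix over usable sites; NA where undefined
.r2_matrix <- function(dos) {
  if (anyNA(dos))
    suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs")^2)
  else
    suppressWarnings(stats::cor(dos)^2)
}

#' Kelly's Zns: mean pairwise r^2 in a window
#'
#' Mean of \code{\link{rh_r2}} over all pairs of usable (polymorphic
#' among non-missing entries) sites; pairs where r^2 is undefined are
#' excluded from both numerator and denominator.
#'
#' @inheritParams pi_dosage
#' @return numeric in [0, 1]; 0 when fewer than two usable sites.
#' @export
zns <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  use <- .usable_sites(dos)
  if (length(use) < 2L) return(0)
  .zns_from_r2(.r2_matrix(dos[, use, drop = FALSE]))
}

.zns_from_r2 <- function(r2) {
  vals <- r2[upper.tri(r2)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(0)
  mean(vals)
}

#' Maximum of the omega statistic over block splits
#'
#' For S usable sites and a split index l in [2, S-2], omega(l) contrasts
#' the mean r^2 within the left block (sites 1..l) and right block (sites
#' l+1..S) against the mean r^2 between blocks:
#' \deqn{\omega(l) = \frac{(C(l,2)+C(S-l,2))^{-1} (\sum r^2_{left} +
#'   \sum r^2_{right})}{(l(S-l))^{-1} \sum r^2_{between}}}
#' The maximum over l is returned. Undefined r^2 values contribute 0 to
#' the sums; splits whose between-block sum is 0 are skipped, and 0 is
#' returned when S < 4 or every split is skipped.
#'
#' @inheritParams pi_dosage
#' @return non-negative numeric scalar.
#' @export
omega_max <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  use <- .usable_sites(dos)
  if (length(use) < 4L) return(0)
  .omega_from_r2(.r2_matrix(dos[, use, drop = FALSE]))
}

.omega_from_r2 <- function(r2) {
  S <- ncol(r2)
  r2[is.na(r2)] <- 0
  diag(r2) <- 0
  # incremental block sums over the lower triangle: for split l,
  # s_left(l) covers pairs within 1..l, s_between(l) pairs straddling l
  lt <- r2
  lt[upper.tri(lt, diag = TRUE)] <- 0
  lt_row <- rowSums(lt)
  s_left <- cumsum(lt_row)
  total <- s_left[S]
  tailcol <- apply(lt, 2L, function(v) rev(cumsum(rev(v))))
  tailcol <- rbind(tailcol[-1L, , drop = FALSE], 0)  # row l -> i > l
  rowcum <- t(apply(tailcol, 1L, cumsum))
  l <- 2:(S - 2L)
  s_between <- rowcum[cbind(l, l)]
  s_right <- total - s_left[l] - s_between
  n_within <- choose(l, 2) + choose(S - l, 2)
  w <- ((s_left[l] + s_right) / n_within) / (s_between / (l * (S - l)))
  w <- w[s_between > 0]
  if (length(w) == 0L) return(0)
  max(w)
}

#' Moments of the pairwise-difference distribution
#'
#' For each unordered pair of individuals, the distance is the Manhattan
#' distance between their dosage vectors over jointly non-missing sites.
#' Returns the population (biased) variance, Fisher skewness and excess
#' kurtosis of these distances; skewness and kurtosis are 0 when the
#' variance is 0.
#'
#' @inheritParams pi_dosage
#' @return named numeric vector \code{c(pwdiff_var, pwdiff_skew,
#'   pwdiff_kurt)}.
#' @export
pwdiff_moments <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  n <- nrow(dos)
  if (n < 2L) stop("pairwise-difference moments require >= 2 individuals")
  if (ncol(dos) == 0L || !anyNA(dos)) {
    d <- if (ncol(dos) == 0L) rep(0, choose(n, 2))
    else as.numeric(stats::dist(dos, method = "manhattan"))
  } else {
    d <- numeric(0)
    for (i in seq_len(n - 1L)) {
      xi <- dos[i, ]
      for (j in (i + 1L):n) {
        xj <- dos[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        d <- c(d, sum(abs(xi[ok] - xj[ok])))
      }
    }
  }
  m <- mean(d)
  m2 <- mean((d - m)^2)
  if (m2 == 0) return(c(pwdiff_var = 0, pwdiff_skew = 0, pwdiff_kurt = 0))
  m3 <- mean((d - m)^3)
  m4 <- mean((d - m)^4)
  c(pwdiff_var = m2, pwdiff_skew = m3 / m2^1.5, pwdiff_kurt = m4 / m2^2 - 3)
}

#' All twelve summary statistics for one subwindow
#'
#' @inheritParams pi_dosage
#' @return named numeric vector of length 12 in the fixed feature order:
#'   pi, theta_w, tajimas_d, n_diplotypes, h1, h12, h2_h1, zns, omega_max,
#'   pwdiff_var, pwdiff_skew, pwdiff_kurt.
#' @export
subwindow_stats <- function(dos) {
  dos <- .as_dosage_matrix(dos)
  spec <- diplotype_spectrum(dos)
  hs <- h_stats(spec$freq)
  pw <- if (nrow(dos) >= 2L) pwdiff_moments(dos)
  else c(pwdiff_var = 0, pwdiff_skew = 0, pwdiff_kurt = 0)
  # the LD statistics share one r^2 matrix
  use <- .usable_sites(dos)
  z <- o <- 0
  if (length(use) >= 2L) {
    r2 <- .r2_matrix(dos[, use, drop = FALSE])
    z <- .zns_from_r2(r2)
    if (length(use) >= 4L) o <- .omega_from_r2(r2)
  }
  c(pi = pi_dosage(dos), theta_w = theta_w(dos), tajimas_d = tajimas_d(dos),
    n_diplotypes = spec$n_diplotypes, hs, zns = z, omega_max = o, pw)
}

#' Names of the twelve window statistics, in feature-row order
#' @return character vector of length 12.
#' @export
stat_names <- function() {
  c("pi", "theta_w", "tajimas_d", "n_diplotypes", "h1", "h12", "h2_h1",
    "zns", "omega_max", "pwdiff_var", "pwdiff_skew", "pwdiff_kurt")
}

.as_dosage_matrix <- function(dos) {
  if (is.data.frame(dos)) dos <- as.matrix(dos)
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = 1L)
  storage.mode(dos) <- "double"
  bad <- !is.na(dos) & !(dos %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dos
}
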
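#' Construct a genotype window
#'
#' An unphased diploid dosage matrix over one multi-subwindow region.
#' Sites that are not segregating among non-missing entries are dropped.
#'
#' @param dosages matrix, individuals x sites, entries 0/1/2/NA.
#' @param positions_bp integer site positions, strictly increasing,
#'   within \code{[0, region_length_bp)}.
#' @param region_length_bp region length in bp.
#' @param n_subwindows number of adjacent equal subwindows.
#' @return an object of class \code{"genotype_window"} with fields
#'   \code{dosages}, \code{positions_bp}, \code{region_length_bp} and
#'   \code{subwindow_edges_bp} (n_subwindows + 1 boundaries).
#' @export
genotype_window <- function(dosages, positions_bp, region_length_bp,
                            n_subwindows = 11L) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  positions_bp <- as.numeric(positions_bp)
  if (length(positions_bp) != ncol(dosages))
    stop("positions_bp length must equal the number of sites")
  if (length(positions_bp) &&
      (is.unsorted(positions_bp, strictly = TRUE) ||
       positions_bp[1] < 0 ||
       positions_bp[length(positions_bp)] >= region_length_bp))
    stop("positions must be strictly increasing within [0, region length)")
  w <- structure(list(dosages = dosages, positions_bp = positions_bp,
                      region_length_bp = as.numeric(region_length_bp),
                      subwindow_edges_bp = seq(0, region_length_bp,
                                               length.out = n_subwindows + 1L)),
                 class = "genotype_window")
  drop_nonsegregating(w)
}

#' @exportS3Method base::print
print.genotype_window <- function(x, ...) {
  cat(sprintf("Genotype window: %d individuals x %d segregating sites, %s bp, %d subwindows\n",
              nrow(x$dosages), ncol(x$dosages),
              format(x$region_length_bp, big.mark = ","),
              length(x$subwindow_edges_bp) - 1L))
  invisible(x)
}

#' Number of subwindows in a genotype window
#' @param window a \code{\link{genotype_window}}.
#' @return integer.
#' @export
n_subwindows <- function(window) {
  length(window$subwindow_edges_bp) - 1L
}

#' Extract the dosage submatrix for one subwindow
#' @param window a \code{\link{genotype_window}}.
#' @param k subwindow index, 1-based.
#' @return dosage matrix for the sites falling in subwindow k.
#' @export
subwindow_dosages <- function(window, k) {
  edges <- window$subwindow_edges_bp
  stopifnot(k >= 1L, k <= length(edges) - 1L)
  keep <- window$positions_bp >= edges[k] & window$positions_bp < edges[k + 1L]
  window$dosages[, keep, drop = FALSE]
}

# drop sites monomorphic (or all-missing) among non-missing entries
drop_nonsegregating <- function(window) {
  dos <- window$dosages
  if (ncol(dos) == 0L) return(window)
  n <- 2L * colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  keep <- n >= 2 & alt > 0 & alt < n
  window$dosages <- dos[, keep, drop = FALSE]
  window$positions_bp <- window$positions_bp[keep]
  window
}

#' Define a mask profile
#'
#' A set of half-open intervals (0-based, bp) on the region coordinate
#' system whose sites will be set to missing when applied to a window.
#'
#' @param starts,ends interval bounds; must be sorted, non-overlapping.
#' @param source_id free-text provenance label.
#' @return an object of class \code{"mask_profile"}.
#' @export
mask_profile <- function(starts = numeric(0), ends = numeric(0),
                         source_id = "") {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(ends <= starts)) stop("intervals must have end > start")
  if (length(starts) > 1L &&
      (is.unsorted(starts, strictly = TRUE) ||
       any(starts[-1L] < ends[-length(ends)])))
    stop("intervals must be sorted and non-overlapping")
  structure(list(starts = starts, ends = ends, source_id = source_id),
            class = "mask_profile")
}

#' Read a library of mask profiles
#'
#' Each file is BED-like text with two (or more) whitespace-separated
#' columns, \code{start end}, 0-based half-open, one interval per line.
#'
#' @param paths character vector of file paths.
#' @return list of \code{\link{mask_profile}} objects named by file.
#' @export
read_mask_profiles <- function(paths) {
  out <- lapply(paths, function(p) {
    tab <- utils::read.table(p, header = FALSE, comment.char = "#")
    mask_profile(tab[[1]], tab[[2]], source_id = basename(p))
  })
  names(out) <- basename(paths)
  out
}

#' Apply a mask profile to a simulated replicate or genotype window
#'
#' Dosages at sites inside masked intervals are set to missing for all
#' individuals; sites that thereby stop segregating are dropped. The
#' operation is idempotent.
#'
#' @param x a \code{\link{sim_replicate}} or \code{\link{genotype_window}}.
#' @param profile a \code{\link{mask_profile}} (empty profile is a no-op).
#' @return the masked object, same class as \code{x}.
#' @export
apply_mask <- function(x, profile) {
  stopifnot(inherits(profile, "mask_profile"))
  win <- if (inherits(x, "sim_replicate")) x$window else x
  if (length(profile$starts)) {
    if (any(profile$starts < 0) || any(profile$ends > win$region_length_bp))
      stop("mask intervals must lie within the region")
    pos <- win$positions_bp
    masked <- rep(FALSE, length(pos))
    for (i in seq_along(profile$starts))
      masked <- masked | (pos >= profile$starts[i] & pos < profile$ends[i])
    win$dosages[, masked] <- NA_real_
    win <- drop_nonsegregating(win)
  }
  if (inherits(x, "sim_replicate")) { x$window <- win; x } else win
}

#' Fraction of a region covered by mask intervals
#' @param profile a \code{\link{mask_profile}}.
#' @param region_length_bp region length.
#' @return numeric in [0, 1].
#' @export
masked_fraction <- function(profile, region_length_bp) {
  sum(profile$ends - profile$starts) / region_length_bp
}
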
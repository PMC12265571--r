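#' Compute the raw 12 x n-subwindow feature matrix for a window
#'
#' Each of the twelve summary statistics (see \code{\link{stat_names}})
#' is computed independently within each subwindow. Subwindows with no
#' usable sites yield the statistics' degenerate values (0) and a warning.
#'
#' @param window a \code{\link{genotype_window}}.
#' @param window_id identifier carried in the result.
#' @return a \code{"feature_matrix"}: numeric matrix, 12 rows (statistics,
#'   in fixed order) x n_subwindows columns, with attributes
#'   \code{window_id} and \code{normalized = FALSE}.
#' @export
compute_features <- function(window, window_id = "") {
  stopifnot(inherits(window, "genotype_window"))
  k <- n_subwindows(window)
  vals <- matrix(0, nrow = 12L, ncol = k,
                 dimnames = list(stat_names(), NULL))
  empty <- integer(0)
  for (j in seq_len(k)) {
    dos <- subwindow_dosages(window, j)
    if (ncol(dos) == 0L) empty <- c(empty, j)
    vals[, j] <- subwindow_stats(dos)
  }
  if (length(empty))
    warning(sprintf("subwindow(s) %s contain no usable sites",
                    paste(empty, collapse = ", ")))
  structure(vals, window_id = window_id, normalized = FALSE,
            class = c("feature_matrix", "matrix", "array"))
}

#' Normalize one row of raw feature values
#'
#' The proportional normalization with the negative-shift rule: if the
#' smallest of the values is below 0, its absolute value is added to every
#' entry; the row is then divided by its sum. A row whose shifted sum is
#' 0 is returned as all zeros.
#'
#' @param row numeric vector of finite values (one statistic across the
#'   subwindows).
#' @return non-negative vector summing to 1 (or all zeros).
#' @export
normalize_row <- function(row) {
  if (any(!is.finite(row))) stop("feature rows must be finite")
  m <- min(row)
  if (m < 0) row <- row + abs(m)
  s <- sum(row)
  if (s == 0) return(rep(0, length(row)))
  row / s
}

#' Normalize a raw feature matrix row-wise
#'
#' @param features a \code{"feature_matrix"} from
#'   \code{\link{compute_features}}.
#' @return the normalized \code{"feature_matrix"}
#'   (\code{normalized = TRUE}).
#' @export
normalize_features <- function(features) {
  out <- t(apply(features, 1L, normalize_row))
  dimnames(out) <- dimnames(features)
  structure(out, window_id = attr(features, "window_id"),
            normalized = TRUE,
            class = c("feature_matrix", "matrix", "array"))
}

#' Compute normalized features for a window in one step
#' @inheritParams compute_features
#' @return normalized \code{"feature_matrix"}.
#' @export
featurize_window <- function(window, window_id = "") {
  normalize_features(compute_features(window, window_id))
}

#' Flatten a feature matrix to the 132-length feature vector
#'
#' Row-major flattening: all subwindow values of the first statistic,
#' then the second, and so on; names are \code{"stat_subwindowIndex"}
#' with 0-based subwindow indices.
#'
#' @param features a \code{"feature_matrix"}.
#' @return named numeric vector.
#' @export
feature_vector <- function(features) {
  k <- ncol(features)
  v <- as.numeric(t(features))
  names(v) <- paste(rep(rownames(features), each = k),
                    rep(seq_len(k) - 1L, times = nrow(features)), sep = "_")
  v
}

#' Write a feature table as TSV
#'
#' One row per window: \code{window_id, chrom, start, end} then the named
#' feature columns. Values are written at full precision so a read/write
#' round trip is bit-exact.
#'
#' @param tab data.frame as produced by pipeline steps: columns
#'   \code{window_id}, \code{chrom}, \code{start}, \code{end} plus
#'   feature columns.
#' @param path output path.
#' @export
write_feature_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{\link{write_feature_table}}
#' @param path file path.
#' @return data.frame with numeric feature columns.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE)
  for (j in setdiff(names(tab), c("window_id", "chrom")))
    tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Assemble the feature-vector design matrix for a list of replicates
#'
#' @param reps list of \code{sim_replicate} objects.
#' @return list with \code{x} (matrix, one row per replicate, 132
#'   columns) and \code{y} (factor of class labels in the fixed class
#'   order).
#' @export
replicate_features <- function(reps) {
  vecs <- lapply(seq_along(reps), function(i) {
    suppressWarnings(
      feature_vector(featurize_window(reps[[i]]$window,
                                      window_id = sprintf("rep_%d", i))))
  })
  x <- do.call(rbind, vecs)
  y <- factor(vapply(reps, function(r) r$label, character(1)),
              levels = sweep_classes())
  list(x = x, y = y)
}
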
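#' Call sweeps from per-window posteriors
#'
#' A window is called a sweep when its argmax class is hard or soft and
#' its combined sweep probability \code{p_hard + p_soft} is greater than
#' or equal to the threshold; the called class is the argmax.
#'
#' @param post a \code{"class_posterior"} data.frame; extra columns (for
#'   example window coordinates) are carried through.
#' @param t threshold in [0, 1]; the reference operating points are 0,
#'   0.80, 0.90, 0.95 and 0.99.
#' @return data.frame of calls with \code{window_id},
#'   \code{called_class} and \code{combined_sweep_prob}, plus any extra
#'   columns of \code{post}.
#' @export
call_sweeps <- function(post, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  pred <- .posterior_argmax(post)
  combined <- post$p_hard + post$p_soft
  keep <- pred %in% c("hard", "soft") & combined >= t
  out <- post[keep, , drop = FALSE]
  out$called_class <- pred[keep]
  out$combined_sweep_prob <- combined[keep]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' q-values for sweep calls from a neutral-simulation null
#'
#' For each call, its own combined sweep probability is treated as a
#' threshold t: the expected number of false positives is the fraction of
#' neutral simulations whose combined sweep probability reaches t, scaled
#' by the number of windows scanned; the FDR at t is that expectation
#' divided by the number of calls at or above t, capped at 1. q-values
#' are the running minimum of the FDR over all less-stringent thresholds
#' (step-up), so they are monotone non-increasing in the combined sweep
#' probability.
#'
#' @param calls data.frame from \code{\link{call_sweeps}}.
#' @param neutral_scores combined sweep probabilities
#'   (\code{p_hard + p_soft}) of neutral simulations — the null; may also
#'   be a \code{"class_posterior"} data.frame.
#' @param n_windows_scanned number of windows scanned genome-wide.
#' @return \code{calls} with columns \code{fdr} and \code{q_value} added,
#'   sorted by decreasing combined sweep probability.
#' @export
fdr_and_q <- function(calls, neutral_scores, n_windows_scanned) {
  if (is.data.frame(neutral_scores))
    neutral_scores <- neutral_scores$p_hard + neutral_scores$p_soft
  if (length(neutral_scores) < 1L)
    stop("at least one neutral simulation is required")
  if (nrow(calls) == 0L) {
    calls$fdr <- numeric(0)
    calls$q_value <- numeric(0)
    return(calls)
  }
  calls <- calls[order(calls$combined_sweep_prob, decreasing = TRUE), ,
                 drop = FALSE]
  t_i <- calls$combined_sweep_prob
  n_ge <- seq_along(t_i)           # calls at or above each threshold
  # ties: every call with the same threshold shares the largest rank
  n_ge <- ave(n_ge, t_i, FUN = max)
  e_fp <- vapply(t_i, function(t) mean(neutral_scores >= t),
                 numeric(1)) * n_windows_scanned
  fdr <- pmin(1, e_fp / n_ge)
  # step-up: ascending threshold order, running minimum
  asc <- rev(seq_along(t_i))
  q_asc <- cummin(fdr[asc])
  calls$fdr <- fdr
  calls$q_value <- rev(q_asc)
  rownames(calls) <- NULL
  calls
}

#' Conservative estimate of the fraction of sweeps that are soft
#'
#' Applies two corrections to observed hard/soft call counts, both of
#' which can only lower the soft fraction: (1) all expected false
#' discoveries at the threshold (\code{q_at_t} times the total calls) are
#' assumed to be soft calls and subtracted; (2) the estimated number of
#' true hard sweeps, \code{n_hard_obs / c_hh}, is multiplied by the
#' hard-called-soft confusion fraction \code{c_hs} to estimate hard
#' sweeps misattributed to the soft class, which are moved from soft to
#' hard. Misclassification of soft sweeps as hard is deliberately
#' ignored, making the estimate a lower bound.
#'
#' @param n_hard_obs,n_soft_obs observed call counts at the threshold.
#' @param q_at_t q-value at the threshold.
#' @param c_hh confusion fraction: true hard called hard (> 0).
#' @param c_hs confusion fraction: true hard called soft.
#' @return list of class \code{"soft_fraction_estimate"} with the
#'   intermediate quantities and \code{proportion_soft}.
#' @export
soft_fraction_corrected <- function(n_hard_obs, n_soft_obs, q_at_t,
                                    c_hh, c_hs) {
  if (q_at_t < 0 || q_at_t > 1) stop("q_at_t must lie in [0, 1]")
  if (n_hard_obs < 0 || n_soft_obs < 0) stop("counts must be >= 0")
  if (c_hh <= 0) {
    if (n_hard_obs > 0)
      stop("c_hh = 0 with observed hard calls: calibration uninterpretable")
    c_hh <- 1
  }
  fd <- q_at_t * (n_hard_obs + n_soft_obs)
  soft1 <- max(0, n_soft_obs - fd)
  misattributed <- (n_hard_obs / c_hh) * c_hs
  soft_adj <- max(0, soft1 - misattributed)
  hard_adj <- n_hard_obs + misattributed
  prop <- if (soft_adj + hard_adj == 0) NA_real_
  else soft_adj / (soft_adj + hard_adj)
  structure(list(n_hard_obs = n_hard_obs, n_soft_obs = n_soft_obs,
                 q_at_t = q_at_t, c_hh = c_hh, c_hs = c_hs,
                 expected_false_discoveries = fd,
                 soft_adjusted = soft_adj, hard_adjusted = hard_adj,
                 proportion_soft = prop),
            class = "soft_fraction_estimate")
}

#' @exportS3Method base::print
print.soft_fraction_estimate <- function(x, ...) {
  cat(sprintf("Soft-sweep fraction (conservative): %.4f\n",
              x$proportion_soft))
  cat(sprintf("  observed %d hard / %d soft; expected false discoveries %.2f\n",
              x$n_hard_obs, x$n_soft_obs, x$expected_false_discoveries))
  cat(sprintf("  adjusted %.2f hard / %.2f soft\n", x$hard_adjusted,
              x$soft_adjusted))
  invisible(x)
}

#' Percentage of calls that are soft, table-formatted
#'
#' \code{100 * n_soft / (n_hard + n_soft)}, rounded half-up to one
#' decimal through an intermediate two-decimal rounding (the convention
#' used for the package's summary tables).
#'
#' @param n_hard,n_soft call counts.
#' @return numeric percentage, or NA when there are no calls.
#' @export
percent_soft <- function(n_hard, n_soft) {
  tot <- n_hard + n_soft
  if (tot == 0) return(NA_real_)
  pct <- 100 * n_soft / tot
  half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits
  half_up(half_up(pct, 2L), 1L)
}

#' Summary of hard/soft call counts per sample and threshold
#'
#' @param calls_by_sample named list; each element is a
#'   \code{"class_posterior"} data.frame for one sample.
#' @param thresholds probability thresholds (0 means no cutoff).
#' @return data.frame with one row per (sample, threshold):
#'   \code{n_hard}, \code{n_soft} and \code{percent_soft}.
#' @export
count_table <- function(calls_by_sample,
                        thresholds = c(0, 0.80, 0.90, 0.95, 0.99)) {
  rows <- list()
  for (sample in names(calls_by_sample)) {
    post <- calls_by_sample[[sample]]
    for (t in thresholds) {
      calls <- call_sweeps(post, t)
      n_hard <- sum(calls$called_class == "hard")
      n_soft <- sum(calls$called_class == "soft")
      rows[[length(rows) + 1L]] <-
        data.frame(sample = sample, threshold = t, n_hard = n_hard,
                   n_soft = n_soft,
                   percent_soft = percent_soft(n_hard, n_soft))
    }
  }
  do.call(rbind, rows)
}

#' Cross-sample sharing of sweep windows
#'
#' Partitions the distinct windows called in any sample by the exact
#' subset of samples in which each is called.
#'
#' @param calls_by_sample named list of call data.frames (from
#'   \code{\link{call_sweeps}}), windows identified by \code{window_id};
#'   the identifiers must come from a common window grid.
#' @return data.frame with \code{subset} (sample names joined by
#'   \code{+}), \code{n_samples}, \code{count} and \code{percent} of the
#'   distinct-window total.
#' @export
sharing_report <- function(calls_by_sample) {
  if (length(calls_by_sample) < 1L) stop("at least one sample is required")
  ids <- lapply(calls_by_sample, function(x) unique(x$window_id))
  all_ids <- unique(unlist(ids))
  if (length(all_ids) == 0L)
    return(data.frame(subset = character(0), n_samples = integer(0),
                      count = integer(0), percent = numeric(0)))
  membership <- vapply(seq_along(ids), function(i) all_ids %in% ids[[i]],
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids))
  subset_key <- apply(membership, 1L, function(m)
    paste(names(calls_by_sample)[m], collapse = "+"))
  tab <- table(subset_key)
  out <- data.frame(subset = names(tab),
                    n_samples = lengths(strsplit(names(tab), "+",
                                                 fixed = TRUE)),
                    count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(all_ids),
                    row.names = NULL)
  out[order(-out$n_samples, out$subset), , drop = FALSE]
}

#' Write sweep calls as BED-like TSV
#'
#' Columns: chrom, focal start, focal end, called class, combined sweep
#' probability, q-value. Windows missing coordinate columns are written
#' with their window_id in place of chrom.
#'
#' @param calls data.frame from \code{\link{fdr_and_q}}.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  has_coord <- all(c("chrom", "focal_start", "focal_end") %in% names(calls))
  out <- if (has_coord)
    calls[, c("chrom", "focal_start", "focal_end", "called_class",
              "combined_sweep_prob", "q_value")]
  else cbind(calls["window_id"],
             calls[, c("called_class", "combined_sweep_prob", "q_value")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
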
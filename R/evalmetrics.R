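#' Confusion matrix at a sweep-probability threshold
#'
#' Predicted class is the argmax posterior. An example whose argmax is
#' hard or soft but whose combined sweep probability
#' (\code{p_hard + p_soft}) falls below the threshold is treated as
#' uncertain and excluded from the per-class fraction denominators.
#'
#' @param post a \code{"class_posterior"} data.frame
#'   (\code{\link{predict_posterior}}).
#' @param truth factor or character vector of true classes.
#' @param t threshold in [0, 1].
#' @return list of class \code{"confusion_matrix"}: \code{threshold},
#'   \code{counts} (5 x 5 true x predicted, classified examples only),
#'   \code{fractions} (row-normalized), \code{n_uncertain} (per true
#'   class).
#' @export
confusion_at_threshold <- function(post, truth, t) {
  if (nrow(post) == 0L) stop("empty posterior table")
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  truth <- factor(truth, levels = sweep_classes())
  if (length(truth) != nrow(post)) stop("posterior/truth size mismatch")
  pred <- factor(.posterior_argmax(post), levels = sweep_classes())
  sweep_prob <- post$p_hard + post$p_soft
  uncertain <- pred %in% c("hard", "soft") & sweep_prob < t
  counts <- table(truth = truth[!uncertain], predicted = pred[!uncertain])
  counts <- unclass(counts)
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs == 0, 1, rs)
  tab_unc <- table(truth[uncertain])
  n_uncertain <- as.integer(tab_unc[match(sweep_classes(), names(tab_unc))])
  n_uncertain[is.na(n_uncertain)] <- 0L
  names(n_uncertain) <- sweep_classes()
  structure(list(threshold = t, counts = counts, fractions = fractions,
                 n_uncertain = n_uncertain,
                 n_classified = sum(counts)),
            class = "confusion_matrix")
}

#' @exportS3Method base::print
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix at threshold %.2f (%d classified, %d uncertain)\n",
              x$threshold, x$n_classified, sum(x$n_uncertain)))
  print(round(x$fractions, 3))
  invisible(x)
}

#' ROC and precision-recall curves for sweep-vs-unselected
#'
#' Collapses the five classes to the binary task of distinguishing
#' selective sweeps (hard or soft) from unselected regions (sweep-linked
#' or neutral). The score is the combined sweep probability
#' \code{p_hard + p_soft}; equal scores are grouped into a single
#' operating point. AUC uses the trapezoid rule; average precision is
#' the step-wise sum \code{sum((R_n - R_{n-1}) * P_n)}.
#'
#' @inheritParams confusion_at_threshold
#' @return list with \code{roc} (data.frame fpr/tpr), \code{auc},
#'   \code{pr} (data.frame recall/precision) and \code{ap}.
#' @export
roc_pr <- function(post, truth) {
  truth <- factor(truth, levels = sweep_classes())
  pos <- truth %in% c("hard", "soft")
  if (!any(pos) || all(pos))
    stop("both sweep and unselected examples are required")
  score <- post$p_hard + post$p_soft
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  pos <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  P <- sum(pos); N <- length(pos) - P
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = recall, precision = precision), ap = ap)
}

#' Write evaluation metrics to disk
#'
#' JSON with the AUC, AP and per-threshold confusion matrices, plus TSV
#' curve files alongside.
#'
#' @param eval_list list with elements \code{roc_pr} (from
#'   \code{\link{roc_pr}}) and \code{confusions} (list of
#'   \code{confusion_matrix} objects).
#' @param dir output directory.
#' @export
write_metrics <- function(eval_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- lapply(eval_list$confusions, function(cm)
    list(threshold = cm$threshold, counts = cm$counts,
         fractions = cm$fractions, n_uncertain = cm$n_uncertain))
  jsonlite::write_json(list(auc = eval_list$roc_pr$auc,
                            ap = eval_list$roc_pr$ap,
                            confusion_matrices = conf),
                       file.path(dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(eval_list$roc_pr$roc, file.path(dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eval_list$roc_pr$pr, file.path(dir, "pr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
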
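#' Read diploid genotypes from a VCF into a genotype window
#'
#' Biallelic SNP records inside the region are converted to alternate
#' allele dosages (0/1/2, NA for uncalled genotypes); multi-allelic and
#' non-SNP records are skipped and counted. VCF positions are 1-based;
#' the region is 0-based half-open and window coordinates are expressed
#' relative to its start.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param chrom chromosome name.
#' @param start,end region bounds, 0-based half-open.
#' @param n_subwindows number of subwindows for the resulting window.
#' @return a \code{\link{genotype_window}}; the number of skipped records
#'   is attached as attribute \code{"n_skipped"}.
#' @export
read_genotypes <- function(vcf_path, chrom, start, end,
                           n_subwindows = 11L) {
  .window_from_vcf(.read_vcf_dosages(vcf_path), chrom, start, end,
                   n_subwindows)
}

# parse a whole VCF once: chrom/pos/dosage matrix plus skip counts
.read_vcf_dosages <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  pos1 <- as.numeric(fix[, "POS"])
  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) & !is.na(fix[, "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos1))
  gt <- gt[snp, , drop = FALSE]
  uniq <- unique(as.vector(gt))
  lut <- vapply(uniq, .gt_to_dosage, numeric(1))
  dos <- matrix(lut[match(as.vector(gt), uniq)], nrow = nrow(gt))
  list(chrom = fix[snp, "CHROM"], pos1 = pos1[snp],
       dos = t(dos), n_skipped_total = sum(!snp))
}

# cut one region out of a parsed VCF as a genotype window
.window_from_vcf <- function(parsed, chrom, start, end, n_subwindows) {
  keep <- parsed$chrom == chrom & parsed$pos1 >= start + 1 &
    parsed$pos1 <= end
  win <- genotype_window(parsed$dos[, keep, drop = FALSE],
                         parsed$pos1[keep] - 1 - start, end - start,
                         n_subwindows)
  attr(win, "n_skipped") <- parsed$n_skipped_total
  win
}

# genotype string -> dosage; any missing allele makes the call missing
.gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Enumerate sliding scan windows along a chromosome
#'
#' One window per focal subwindow whose full context (focal subwindow
#' plus flanking subwindows on each side) fits on the chromosome; the
#' step equals the focal size, so with a 250 kb focal size and 11
#' subwindows each window is a 2.75 Mb context classified at its central
#' 250 kb.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param focal_size focal subwindow size in bp (default 250 kb).
#' @param n_subwindows context size in subwindows (odd, default 11).
#' @return data.frame of scan windows: \code{chrom},
#'   \code{focal_start}, \code{focal_end}, \code{context_start},
#'   \code{context_end} (0-based half-open); empty when the chromosome is
#'   shorter than one context.
#' @export
enumerate_windows <- function(chrom, chrom_length, focal_size = 250000,
                              n_subwindows = 11L) {
  flank <- (n_subwindows - 1L) %/% 2L
  n_slots <- floor(chrom_length / focal_size)
  slots <- seq_len(n_slots) - 1L
  slots <- slots[slots >= flank & slots + flank + 1L <= n_slots]
  if (length(slots) == 0L)
    return(data.frame(chrom = character(0), focal_start = numeric(0),
                      focal_end = numeric(0), context_start = numeric(0),
                      context_end = numeric(0)))
  data.frame(chrom = chrom,
             focal_start = slots * focal_size,
             focal_end = (slots + 1) * focal_size,
             context_start = (slots - flank) * focal_size,
             context_end = (slots + flank + 1) * focal_size)
}

#' Read a BED mask file
#'
#' @param path BED file: chrom, start, end (0-based half-open).
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed_mask <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  stats::setNames(tab[, 1:3], c("chrom", "start", "end"))
}

#' Read a tabular recombination map
#'
#' @param path whitespace-separated text: chrom, start, end, rate
#'   (per bp per generation), 0-based half-open intervals.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{rate}.
#' @export
read_recomb_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  stats::setNames(tab[, 1:4], c("chrom", "start", "end", "rate"))
}

# overlap length of [s, e) with a set of intervals on one chromosome
.overlap_bp <- function(s, e, starts, ends) {
  lo <- pmax(s, starts)
  hi <- pmin(e, ends)
  sum(pmax(0, hi - lo))
}

#' Length-weighted mean recombination rate over an interval
#'
#' Spans of the interval not covered by the map contribute rate 0.
#'
#' @param map recombination map data.frame
#'   (\code{\link{read_recomb_map}}).
#' @param chrom,start,end interval, 0-based half-open.
#' @return mean rate per bp per generation.
#' @export
mean_recomb_rate <- function(map, chrom, start, end) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  lo <- pmax(start, m$start)
  hi <- pmin(end, m$end)
  w <- pmax(0, hi - lo)
  sum(w * m$rate) / (end - start)
}

#' Apply the scan-window quality filters
#'
#' A window is dropped when the length-weighted mean recombination rate
#' over its context is zero, or when the fraction of context bp covered
#' by the mask exceeds \code{masked_fraction_max} (strictly).
#'
#' @param window one row of \code{\link{enumerate_windows}} output.
#' @param mask mask data.frame (\code{\link{read_bed_mask}}); may be
#'   empty.
#' @param map recombination map data.frame.
#' @param masked_fraction_max maximum tolerated masked fraction
#'   (default 0.85).
#' @return list with \code{keep} (logical), \code{reason} (\code{NA},
#'   \code{"zero_recombination"} or \code{"masked_fraction"}),
#'   \code{masked_fraction} and \code{mean_rate}.
#' @export
window_filters <- function(window, mask, map,
                           masked_fraction_max = 0.85) {
  m <- mask[mask$chrom == window$chrom, , drop = FALSE]
  mf <- if (nrow(m) == 0L) 0
  else .overlap_bp(window$context_start, window$context_end,
                   m$start, m$end) /
    (window$context_end - window$context_start)
  rate <- mean_recomb_rate(map, window$chrom, window$context_start,
                           window$context_end)
  if (rate == 0)
    return(list(keep = FALSE, reason = "zero_recombination",
                masked_fraction = mf, mean_rate = rate))
  if (mf > masked_fraction_max)
    return(list(keep = FALSE, reason = "masked_fraction",
                masked_fraction = mf, mean_rate = rate))
  list(keep = TRUE, reason = NA_character_, masked_fraction = mf,
       mean_rate = rate)
}

#' Scan a genome: features and posteriors for every kept window
#'
#' Enumerates sliding windows over each chromosome, applies the
#' recombination and masked-fraction filters, builds the 11-subwindow
#' genotype context for each kept window (masked intervals set missing),
#' computes normalized features and classifies them. Deterministic given
#' the inputs and the model.
#'
#' @param vcf_path VCF of unphased diploid genotypes.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param mask mask data.frame (\code{\link{read_bed_mask}}) or NULL.
#' @param map recombination map data.frame
#'   (\code{\link{read_recomb_map}}).
#' @param model a fitted \code{"sweep_classifier"}.
#' @param focal_size focal subwindow size in bp.
#' @param n_subwindows context size in subwindows.
#' @param masked_fraction_max window filter bound.
#' @return data.frame: one row per kept window with coordinates,
#'   \code{masked_fraction}, \code{mean_rate}, the five posteriors and
#'   \code{argmax_class}.
#' @export
scan_genome <- function(vcf_path, chrom_lengths, mask, map, model,
                        focal_size = 250000, n_subwindows = 11L,
                        masked_fraction_max = 0.85) {
  if (is.null(mask))
    mask <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  parsed <- .read_vcf_dosages(vcf_path)
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    wins <- enumerate_windows(chrom, chrom_lengths[[chrom]], focal_size,
                              n_subwindows)
    for (i in seq_len(nrow(wins))) {
      w <- wins[i, ]
      filt <- window_filters(w, mask, map, masked_fraction_max)
      if (!filt$keep) next
      win <- .window_from_vcf(parsed, chrom, w$context_start,
                              w$context_end, n_subwindows)
      m <- mask[mask$chrom == chrom, , drop = FALSE]
      if (nrow(m) > 0L) {
        loc <- data.frame(start = pmax(0, m$start - w$context_start),
                          end = pmin(w$context_end - w$context_start,
                                     m$end - w$context_start))
        loc <- loc[loc$end > loc$start, , drop = FALSE]
        if (nrow(loc) > 0L)
          win <- apply_mask(win, mask_profile(loc$start, loc$end))
      }
      wid <- sprintf("%s:%.0f-%.0f", chrom, w$focal_start, w$focal_end)
      row <- tryCatch({
        feats <- suppressWarnings(featurize_window(win, window_id = wid))
        post <- predict_posterior(model, feats, window_id = wid)
        cbind(data.frame(chrom = chrom, focal_start = w$focal_start,
                         focal_end = w$focal_end,
                         masked_fraction = filt$masked_fraction,
                         mean_rate = filt$mean_rate),
              post, data.frame(argmax_class = .posterior_argmax(post)))
      }, error = function(e) {
        warning(sprintf("window %s skipped: %s", wid,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L)
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
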
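# Marker-panel selection for reduced-complexity crosses (RCC): strain-unique
# SNPs that are homozygous-discordant (1/1 in one substrain, 0/0 in the
# other), well genotyped in both, outside soft-masked repeats, thinned to the
# single best marker per fixed genomic window.

#' Candidate RCC markers
#'
#' From classified strain-unique SNPs, keeps biallelic homozygous-discordant
#' calls (exactly 1/1 vs 0/0), requires GQ >= `gq_min` in both samples,
#' drops positions inside soft-masked repeats, and assigns each candidate to
#' a fixed window of `window_size` bp anchored at `anchor` (1-based) on its
#' chromosome: `window_index = floor((pos - anchor) / window_size)`.
#'
#' @param classified output of [classify_variants()] (only rows with
#'   var_class "SNP" and category unique_A/unique_B are considered).
#' @param mask named list of IRanges of soft-masked intervals
#'   ([softmask_ranges()] or [mask_from_bed()]); NULL disables masking.
#' @param gq_min minimum GQ in both samples (inclusive).
#' @param window_size window width in bp (default 3 Mb).
#' @param anchor 1-based position where window 0 starts on every chromosome.
#' @return data.frame of candidates: chrom, pos, ref, alt, category,
#'   genotype_A, genotype_B, gq_A, gq_B, avg_gq, min_gq, window_index.
#' @export
candidate_markers <- function(classified, mask = NULL, gq_min = 30,
                              window_size = 3e6, anchor = 1L) {
  x <- classified[classified$var_class == "SNP" &
                    classified$category %in% c("unique_A", "unique_B"), ,
                  drop = FALSE]
  hom_disc <- (norm_gt(x$gt_A) == "1/1" & norm_gt(x$gt_B) == "0/0") |
              (norm_gt(x$gt_A) == "0/0" & norm_gt(x$gt_B) == "1/1")
  x <- x[!is.na(hom_disc) & hom_disc, , drop = FALSE]
  gq_ok <- !is.na(x$gq_A) & !is.na(x$gq_B) & x$gq_A >= gq_min & x$gq_B >= gq_min
  x <- x[gq_ok, , drop = FALSE]
  if (!is.null(mask) && nrow(x))
    x <- x[!is_masked(mask, x$chrom, x$pos), , drop = FALSE]
  out <- data.frame(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
    category = x$category,
    genotype_A = x$gt_A, genotype_B = x$gt_B,
    gq_A = x$gq_A, gq_B = x$gq_B,
    avg_gq = (x$gq_A + x$gq_B) / 2,
    min_gq = pmin(x$gq_A, x$gq_B),
    window_index = as.integer(floor((x$pos - anchor) / window_size)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  attr(out, "anchor") <- anchor
  out
}

#' Select the marker panel: one best SNP per window
#'
#' Within every non-empty (chromosome, window) cell, selects the candidate
#' with the highest average GQ; ties are broken by higher minimum GQ, then by
#' smaller position, making selection total and deterministic.
#'
#' @param candidates output of [candidate_markers()].
#' @return data.frame (class `marker_panel`) with the same columns as the
#'   candidates, one row per occupied window, ordered by chrom then pos;
#'   window size and anchor carried in attributes.
#' @export
select_panel <- function(candidates) {
  if (nrow(candidates) == 0L) {
    out <- candidates
  } else {
    o <- order(candidates$chrom, candidates$window_index,
               -candidates$avg_gq, -candidates$min_gq, candidates$pos)
    s <- candidates[o, , drop = FALSE]
    first <- !duplicated(paste(s$chrom, s$window_index))
    out <- s[first, , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "window_size") <- attr(candidates, "window_size")
  attr(out, "anchor") <- attr(candidates, "anchor")
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Panel quality-control report
#'
#' Per-chromosome marker counts, the largest gap between consecutive markers,
#' and the windows left without a marker.
#'
#' @param panel output of [select_panel()].
#' @param chrom_lengths named vector of chromosome lengths (bp), defining the
#'   full window grid.
#' @param window_size,anchor window parameters; default to those carried on
#'   the panel.
#' @return list with `per_chrom` (data.frame: chrom, n_markers, n_windows,
#'   max_gap) and `empty_windows` (data.frame: chrom, window_index, start,
#'   end).
#' @export
panel_report <- function(panel, chrom_lengths,
                         window_size = attr(panel, "window_size"),
                         anchor = attr(panel, "anchor")) {
  if (is.null(window_size)) window_size <- 3e6
  if (is.null(anchor)) anchor <- 1L
  per_rows <- list()
  empty_rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n_windows <- ceiling((len - anchor + 1) / window_size)
    p <- panel[panel$chrom == ch, , drop = FALSE]
    occupied <- unique(p$window_index)
    missing <- setdiff(seq_len(n_windows) - 1L, occupied)
    if (length(missing))
      empty_rows[[ch]] <- data.frame(
        chrom = ch, window_index = missing,
        start = anchor + missing * window_size,
        end = pmin(anchor + (missing + 1) * window_size - 1, len),
        stringsAsFactors = FALSE)
    max_gap <- if (nrow(p) >= 2L) max(diff(sort(p$pos))) else NA_real_
    per_rows[[ch]] <- data.frame(chrom = ch, n_markers = nrow(p),
                                 n_windows = n_windows, max_gap = max_gap,
                                 stringsAsFactors = FALSE)
  }
  per_chrom <- do.call(rbind, per_rows)
  rownames(per_chrom) <- NULL
  empty_windows <- if (length(empty_rows)) do.call(rbind, empty_rows) else
    data.frame(chrom = character(), window_index = integer(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  rownames(empty_windows) <- NULL
  list(per_chrom = per_chrom, empty_windows = empty_windows)
}
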
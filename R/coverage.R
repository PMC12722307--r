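# Per-chromosome and genome-wide depth statistics over interval depth tracks.
# All statistics are position-weighted: every reference position contributes
# once, with no sampling, so results are invariant under interval refinement.

#' Coverage bin boundaries
#'
#' Integer-depth bins: zero (0x), low (1 to `low_max`), medium (`low_max`+1 to
#' `medium_max`), high (> `medium_max`). Defaults give the conventional
#' zero / 1-10x / 11-30x / >30x bins.
#'
#' @param low_max upper bound of the low bin (inclusive).
#' @param medium_max upper bound of the medium bin (inclusive).
#' @return list with elements `low_max`, `medium_max`.
#' @export
coverage_bins <- function(low_max = 10, medium_max = 30) {
  stopifnot(low_max > 0, medium_max > low_max)
  list(low_max = low_max, medium_max = medium_max)
}

# Weighted lower median: the depth of the k-th position when positions are
# ordered by depth, with k = L/2 for even L and (L+1)/2 for odd L.
weighted_lower_median <- function(depth, weight) {
  o <- order(depth)
  depth <- depth[o]; weight <- weight[o]
  L <- sum(weight)
  k <- if (L %% 2 == 0) L / 2 else (L + 1) / 2
  depth[which(cumsum(weight) >= k)[1]]
}

coverage_row <- function(chrom, depth, weight, bins) {
  L <- sum(weight)
  mean_d <- sum(depth * weight) / L
  sd_d <- sqrt(sum(weight * (depth - mean_d)^2) / L)
  pct <- function(sel) 100 * sum(weight[sel]) / L
  data.frame(
    chrom = chrom, length = L,
    mean = mean_d,
    median = weighted_lower_median(depth, weight),
    min = min(depth), max = max(depth), sd = sd_d,
    pct_zero = pct(depth == 0),
    pct_low = pct(depth > 0 & depth <= bins$low_max),
    pct_medium = pct(depth > bins$low_max & depth <= bins$medium_max),
    pct_high = pct(depth > bins$medium_max),
    stringsAsFactors = FALSE)
}

#' Summarise coverage of one contig's depth track
#'
#' Computes interval-weighted depth statistics (mean, lower median, min, max,
#' population standard deviation) and the percentage of positions in each
#' coverage bin. The four bin percentages sum to 100.
#'
#' @param track depth-track data.frame for a single contig (chrom, start,
#'   end, depth; 0-based half-open), satisfying the tiling invariant.
#' @param bins bin boundaries from [coverage_bins()].
#' @return one-row data.frame (a `CoverageSummary`): chrom, length, mean,
#'   median, min, max, sd, pct_zero, pct_low, pct_medium, pct_high.
#' @export
summarize_coverage <- function(track, bins = coverage_bins()) {
  if (nrow(track) == 0L) stop("empty depth track")
  if (length(unique(track$chrom)) != 1L)
    stop("summarize_coverage() takes a single contig; see genome_coverage_summary()")
  validate_depth_track(track)
  coverage_row(track$chrom[1], track$depth, track$end - track$start, bins)
}

#' Genome-wide coverage summary across contigs
#'
#' Position-weighted aggregation over all contigs: identical to
#' [summarize_coverage()] applied to the concatenation of the tracks.
#'
#' @param tracks a single depth-track data.frame covering several contigs, or
#'   a list of per-contig tracks. Duplicate contig names across list elements
#'   are an error.
#' @param bins bin boundaries from [coverage_bins()].
#' @return one-row data.frame with `chrom = "genome"`.
#' @export
genome_coverage_summary <- function(tracks, bins = coverage_bins()) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  chroms <- unlist(lapply(tracks, function(t) unique(t$chrom)))
  if (anyDuplicated(chroms)) stop("duplicate contig names across tracks")
  all <- do.call(rbind, tracks)
  if (nrow(all) == 0L) stop("empty depth track")
  validate_depth_track(all)
  coverage_row("genome", all$depth, all$end - all$start, bins)
}

#' Per-contig coverage table for a set of samples
#'
#' Convenience wrapper producing the per-strain, per-chromosome coverage
#' table (plus a genome row per strain).
#'
#' @param tracks named list (by strain) of depth-track data.frames.
#' @param bins bin boundaries.
#' @return data.frame with a `strain` column followed by the
#'   `CoverageSummary` columns.
#' @export
coverage_table <- function(tracks, bins = coverage_bins()) {
  rows <- lapply(names(tracks), function(strain) {
    tr <- tracks[[strain]]
    per <- lapply(split(tr, tr$chrom), summarize_coverage, bins = bins)
    out <- rbind(do.call(rbind, per), genome_coverage_summary(tr, bins))
    cbind(strain = strain, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
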
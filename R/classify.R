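# Quality filtering and shared/unique classification of jointly called
# variants from two inbred substrains.
#
# Small variants (SNPs, indels) are filtered on the joint QUAL score and
# per-sample GQ; structural variants are filtered on FILTER = PASS instead
# (long-read SV callers typically emit no GQ). Sites inside known
# assembly-error regions are excluded outright.

CATEGORIES <- c("shared", "unique_A", "unique_B", "discordant_other",
                "discarded")

#' Classification configuration
#'
#' Thresholds and exclusions for [apply_quality_filters()] and
#' [classify_variants()]. Defaults follow the conventional high-confidence
#' criteria for substrain comparisons: joint QUAL strictly above 30; GQ
#' strictly above 30 in both samples for shared small variants; GQ at least
#' 30 in both samples for strain-unique small variants; SVs must be
#' FILTER = PASS.
#'
#' @param qual_min joint quality threshold; small variants must have
#'   QUAL > `qual_min`.
#' @param gq_min_shared per-sample GQ threshold for shared small variants
#'   (strict: GQ must exceed it).
#' @param gq_min_unique per-sample GQ threshold for strain-unique small
#'   variants (inclusive: GQ >= threshold passes).
#' @param sv_requires_pass if TRUE, SVs lacking PASS in FILTER are discarded.
#' @param excluded_regions optional named list of IRanges (see
#'   [mask_from_bed()]) of known assembly-error regions to exclude.
#' @return list of class `classification_config`.
#' @export
classification_config <- function(qual_min = 30, gq_min_shared = 30,
                                  gq_min_unique = 30,
                                  sv_requires_pass = TRUE,
                                  excluded_regions = NULL) {
  stopifnot(qual_min >= 0, gq_min_shared >= 0, gq_min_unique >= 0)
  structure(list(qual_min = qual_min, gq_min_shared = gq_min_shared,
                 gq_min_unique = gq_min_unique,
                 sv_requires_pass = sv_requires_pass,
                 excluded_regions = excluded_regions),
            class = "classification_config")
}

#' Site-level quality filters
#'
#' Applies, in documented order, (1) the excluded-region filter to all
#' variants, (2) the joint-QUAL filter to small variants, (3) the
#' FILTER = PASS requirement to SVs. The reason reported is the first failed
#' rule. VCF FILTER is deliberately ignored for small variants; QUAL and GQ
#' govern those.
#'
#' @param variants a `variant_table`.
#' @param cfg a [classification_config()].
#' @return data.frame with columns `qc_pass` (logical) and `qc_reason`
#'   (character; NA when passing), one row per variant.
#' @export
apply_quality_filters <- function(variants, cfg = classification_config()) {
  n <- nrow(variants)
  pass <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  if (!is.null(cfg$excluded_regions) && n > 0L) {
    excl <- is_masked(cfg$excluded_regions, variants$chrom, variants$pos)
    pass[excl] <- FALSE
    reason[excl] <- "excluded_region"
  }
  is_sv <- variants$var_class == "SV"
  bad_qual <- pass & !is_sv &
    (is.na(variants$qual) | variants$qual <= cfg$qual_min)
  pass[bad_qual] <- FALSE
  reason[bad_qual] <- "qual"
  if (isTRUE(cfg$sv_requires_pass)) {
    filt <- as.character(variants$filter); filt[is.na(filt)] <- ""
    has_pass <- vapply(strsplit(filt, ";"),
                       function(f) "PASS" %in% f, logical(1))
    bad_sv <- pass & is_sv & !has_pass
    pass[bad_sv] <- FALSE
    reason[bad_sv] <- "filter"
  }
  data.frame(qc_pass = pass, qc_reason = reason, stringsAsFactors = FALSE)
}

#' Bases affected by a variant
#'
#' SNPs affect 1 base; indels affect the largest ref/alt length difference
#' over the called alternate alleles (minimum 1); SVs affect `|sv_len|`
#' bases (minimum 1; SVs without a resolvable length count as 1, with a
#' warning).
#'
#' @param variants a `variant_table`.
#' @return non-negative integer vector (>= 1 for every variant).
#' @export
affected_bases <- function(variants) {
  n <- nrow(variants)
  out <- integer(n)
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  unresolved <- 0L
  for (i in seq_len(n)) {
    cls <- variants$var_class[i]
    if (cls == "SNP") {
      out[i] <- 1L
    } else if (cls == "SV") {
      if (is.na(variants$sv_len[i])) {
        unresolved <- unresolved + 1L
        out[i] <- 1L
      } else out[i] <- max(1L, abs(as.integer(variants$sv_len[i])))
    } else {
      idx <- called_alt_indices(variants$gt_A[i], variants$gt_B[i])
      called <- if (length(idx)) alts[[i]][idx] else alts[[i]]
      out[i] <- max(1L, abs(nchar(called) - nchar(variants$ref[i])))
    }
  }
  if (unresolved > 0L)
    warning(unresolved, " SV(s) without resolvable length counted as 1 base")
  out
}

#' Classify variants as shared, strain-unique, discordant or discarded
#'
#' After the site filters of [apply_quality_filters()], each record is
#' assigned exactly one category:
#' \itemize{
#'   \item \strong{shared}: identical (order-normalised) non-reference
#'     genotypes in both samples; for small variants both GQ must exceed
#'     `gq_min_shared`, for SVs FILTER = PASS stands in for GQ.
#'   \item \strong{unique_A} / \strong{unique_B}: the carrier is
#'     non-reference while the other sample is homozygous reference; for
#'     small variants both GQ must be >= `gq_min_unique`.
#'   \item \strong{discordant_other}: both non-reference but different
#'     genotypes.
#'   \item \strong{discarded}: failed site filters, missing genotype, GQ
#'     below threshold, or homozygous-reference in both samples;
#'     `discard_reason` says which.
#' }
#' Missing GQ fails any GQ threshold. A homozygosity flag (`hom`) records
#' whether the carrier genotype is homozygous-alternate.
#'
#' @param variants a `variant_table`.
#' @param cfg a [classification_config()].
#' @return the input with added columns `zyg_A`, `zyg_B`, `category`,
#'   `discard_reason`, `hom`, `affected_bases`; class `classified_variants`.
#' @export
classify_variants <- function(variants, cfg = classification_config()) {
  qc <- apply_quality_filters(variants, cfg)
  n <- nrow(variants)
  zyg_a <- zygosity(variants$gt_A)
  zyg_b <- zygosity(variants$gt_B)
  ng_a <- norm_gt(variants$gt_A)
  ng_b <- norm_gt(variants$gt_B)
  category <- rep("discarded", n)
  reason <- qc$qc_reason
  is_sv <- variants$var_class == "SV"
  gq_ok_shared <- !is_sv & !is.na(variants$gq_A) & !is.na(variants$gq_B) &
    variants$gq_A > cfg$gq_min_shared & variants$gq_B > cfg$gq_min_shared
  gq_ok_unique <- !is_sv & !is.na(variants$gq_A) & !is.na(variants$gq_B) &
    variants$gq_A >= cfg$gq_min_unique & variants$gq_B >= cfg$gq_min_unique
  # SVs passed FILTER=PASS in qc; that stands in for the GQ requirement
  gq_ok_shared[is_sv] <- TRUE
  gq_ok_unique[is_sv] <- TRUE

  for (i in seq_len(n)) {
    if (!qc$qc_pass[i]) next
    za <- zyg_a[i]; zb <- zyg_b[i]
    if (za == "missing" || zb == "missing") {
      reason[i] <- "missing_genotype"; next
    }
    if (za == "hom_ref" && zb == "hom_ref") {
      reason[i] <- "hom_ref_both"; next
    }
    if (ng_a[i] == ng_b[i]) {                      # identical, non-reference
      if (gq_ok_shared[i]) { category[i] <- "shared"; reason[i] <- NA }
      else reason[i] <- "low_gq"
    } else if (zb == "hom_ref") {                  # A carries, B reference
      if (gq_ok_unique[i]) { category[i] <- "unique_A"; reason[i] <- NA }
      else reason[i] <- "low_gq"
    } else if (za == "hom_ref") {
      if (gq_ok_unique[i]) { category[i] <- "unique_B"; reason[i] <- NA }
      else reason[i] <- "low_gq"
    } else {
      category[i] <- "discordant_other"; reason[i] <- NA
    }
  }
  out <- variants
  out$zyg_A <- zyg_a
  out$zyg_B <- zyg_b
  out$category <- category
  out$discard_reason <- reason
  carrier_zyg <- ifelse(category == "unique_B", zyg_b, zyg_a)
  out$hom <- carrier_zyg == "hom_alt"
  out$affected_bases <- affected_bases(variants)
  class(out) <- c("classified_variants", class(variants))
  out
}

#' Per-chromosome classification summary
#'
#' Counts, homozygosity percentage and mean per-sample GQ for every
#' (chromosome, category, variant class) cell; strain-unique SV cells report
#' mean read coverage (per-sample DP at the site) in place of GQ.
#'
#' @param classified output of [classify_variants()].
#' @return data.frame with columns chrom, category, var_class, n,
#'   homozygous_pct, mean_gq_A, mean_gq_B, mean_cov_A, mean_cov_B.
#' @export
summarize_by_chrom <- function(classified) {
  keep <- classified[classified$category %in%
                       c("shared", "unique_A", "unique_B"), , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(chrom = character(), category = character(),
                      var_class = character(), n = integer(),
                      homozygous_pct = numeric(), mean_gq_A = numeric(),
                      mean_gq_B = numeric(), mean_cov_A = numeric(),
                      mean_cov_B = numeric(), stringsAsFactors = FALSE))
  key <- interaction(keep$chrom, keep$category, keep$var_class, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(keep)), key), function(idx) {
    g <- keep[idx, , drop = FALSE]
    data.frame(
      chrom = g$chrom[1], category = g$category[1], var_class = g$var_class[1],
      n = nrow(g),
      homozygous_pct = 100 * sum(g$hom) / nrow(g),
      mean_gq_A = if (all(is.na(g$gq_A))) NA_real_ else
        mean(g$gq_A, na.rm = TRUE),
      mean_gq_B = if (all(is.na(g$gq_B))) NA_real_ else
        mean(g$gq_B, na.rm = TRUE),
      mean_cov_A = if (all(is.na(g$dp_A))) NA_real_ else
        mean(g$dp_A, na.rm = TRUE),
      mean_cov_B = if (all(is.na(g$dp_B))) NA_real_ else
        mean(g$dp_B, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$category, out$var_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category totals and divergent-base accounting
#'
#' Counts per (category, variant class); the number of divergent sites
#' (strain-unique variants of either strain, all classes) and the bases they
#' affect; the fraction of divergent bases contributed by SVs; and the
#' heterozygous share of shared variants. When `genome_length` is given, the
#' heterozygous and divergent base totals are also expressed as percentages
#' of the genome.
#'
#' @param classified output of [classify_variants()].
#' @param genome_length optional total reference length (bp).
#' @return list with elements `counts` (data.frame category x var_class x n),
#'   `divergent_sites`, `divergent_bases`, `sv_base_pct`,
#'   `shared_het_fraction`, and (if `genome_length`) `divergent_genome_pct`,
#'   `het_genome_pct`.
#' @export
variant_totals <- function(classified, genome_length = NULL) {
  if (nrow(classified) == 0L) {
    counts <- data.frame(category = character(), var_class = character(),
                         n = integer(), stringsAsFactors = FALSE)
    return(list(counts = counts, divergent_sites = 0L, divergent_bases = 0L,
                sv_base_pct = NA_real_, shared_het_fraction = NA_real_))
  }
  tab <- as.data.frame(table(category = classified$category,
                             var_class = classified$var_class),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  rownames(tab) <- NULL
  uniq <- classified$category %in% c("unique_A", "unique_B")
  divergent_sites <- sum(uniq)
  divergent_bases <- sum(classified$affected_bases[uniq])
  sv_bases <- sum(classified$affected_bases[uniq & classified$var_class == "SV"])
  shared <- classified$category == "shared"
  out <- list(
    counts = tab,
    divergent_sites = divergent_sites,
    divergent_bases = divergent_bases,
    sv_base_pct = if (divergent_bases > 0) 100 * sv_bases / divergent_bases
                  else NA_real_,
    shared_het_fraction = if (any(shared)) sum(!classified$hom[shared]) /
        sum(shared) else NA_real_)
  if (!is.null(genome_length)) {
    out$divergent_genome_pct <- 100 * divergent_bases / genome_length
    het_bases <- sum(classified$affected_bases[shared & !classified$hom])
    out$het_genome_pct <- 100 * het_bases / genome_length
  }
  out
}
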
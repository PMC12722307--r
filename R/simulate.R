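# Truth-labelled synthetic dataset generator.
#
# Emulates, at desk scale, the inputs of a two-substrain long-read variant
# comparison: a small multi-chromosome soft-masked reference, a joint
# small-variant VCF dominated by shared homozygous calls with a small
# heterozygous fraction, strain-unique homozygous-discordant variants, GQ
# values straddling the filtering threshold, structural variants with
# PASS/non-PASS FILTER states, SnpEff-style ANN annotations spanning all four
# impact levels, per-sample depth tracks with zero-coverage regions (one
# Y-like chromosome with a large planted zero fraction), and a BED of
# excluded assembly-error regions. Every emitted record has a truth-table row
# recording the intended category and the planted qualities, so each pipeline
# stage can be checked against known truth.

#' Simulation configuration
#'
#' Defaults model a highly inbred substrain pair sequenced at about 40x:
#' mostly shared homozygous variants (heterozygous fraction 0.036, i.e. 96.4
#' percent homozygous), a scaled-down set of strain-unique variants in
#' roughly the 5:2 SNP:indel ratio with a small SV component, 10 percent of
#' GQ values below the 30 threshold, 85 percent of SVs passing FILTER, an
#' impact mix dominated by MODIFIER annotations, and a Y-like chromosome with
#' 34.7 percent zero coverage versus 0.5 percent on autosomes.
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param n_autosomes number of autosome-like contigs (chr1, chr2, ...).
#' @param chrom_length length of every contig in bp (must exceed one marker
#'   window so window boundaries are exercised).
#' @param softmask_fraction fraction of each contig soft-masked (lowercase).
#' @param n_shared_snp,n_shared_indel,n_shared_sv genome-wide shared counts.
#' @param shared_het_fraction probability a shared variant is heterozygous.
#' @param n_unique_A,n_unique_B named vectors `c(snp=, indel=, sv=)` of
#'   strain-unique counts.
#' @param unique_hom_fraction probability the carrier of a strain-unique
#'   small variant is homozygous (1/1) rather than heterozygous.
#' @param gq_below_fraction mass of the GQ mixture below the 30 threshold
#'   (uniform on `gq_below_range`); the rest is normal
#'   (`gq_above_mean`, `gq_above_sd`) truncated to [31, 99].
#' @param gq_below_range,gq_above_mean,gq_above_sd GQ mixture parameters.
#' @param qual_below_fraction fraction of small-variant QUAL values planted
#'   at or below 30 (uniform on (5, 30]); the rest uniform on (35, 95).
#' @param sv_pass_fraction fraction of SV records with FILTER = PASS.
#' @param impact_mix named probabilities over HIGH/MODERATE/LOW/MODIFIER for
#'   small-variant annotations (SVs are annotated MODIFIER).
#' @param depth_mean named vector `c(A=, B=)` of mean sequencing depth.
#' @param zero_frac_autosome,zero_frac_y planted zero-coverage fraction of
#'   autosomes and of the Y-like contig.
#' @param n_genes_per_chrom,gene_length fictitious gene model used to keep
#'   ANN effects consistent with variant positions.
#' @param n_excluded_per_chrom,excluded_length planted assembly-error
#'   regions per contig.
#' @param guard minimum spacing between simulated variants (bp).
#' @param sample_names VCF sample names for strains A and B.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_autosomes = 4L,
    chrom_length = 6.5e6,
    softmask_fraction = 0.10,
    n_shared_snp = 3000L, n_shared_indel = 600L, n_shared_sv = 100L,
    shared_het_fraction = 0.036,
    n_unique_A = c(snp = 506L, indel = 228L, sv = 22L),
    n_unique_B = c(snp = 699L, indel = 279L, sv = 28L),
    unique_hom_fraction = 0.9,
    gq_below_fraction = 0.10,
    gq_below_range = c(5, 30),
    gq_above_mean = 55, gq_above_sd = 8,
    qual_below_fraction = 0.02,
    sv_pass_fraction = 0.85,
    impact_mix = c(HIGH = 0.01, MODERATE = 0.05, LOW = 0.06, MODIFIER = 0.88),
    depth_mean = c(A = 39.2, B = 41.9),
    zero_frac_autosome = 0.005,
    zero_frac_y = 0.347,
    n_genes_per_chrom = 30L, gene_length = 3e4,
    n_excluded_per_chrom = 2L, excluded_length = 5e3,
    guard = 10L,
    sample_names = c(A = "strain_A", B = "strain_B")) {
  stopifnot(softmask_fraction >= 0, softmask_fraction <= 1,
            shared_het_fraction >= 0, shared_het_fraction <= 1,
            gq_below_fraction >= 0, gq_below_fraction <= 1,
            sv_pass_fraction >= 0, sv_pass_fraction <= 1,
            abs(sum(impact_mix) - 1) < 1e-9,
            all(c("snp", "indel", "sv") %in% names(n_unique_A)),
            all(c("snp", "indel", "sv") %in% names(n_unique_B)),
            n_shared_snp >= 0, n_shared_indel >= 0, n_shared_sv >= 0,
            all(n_unique_A >= 0), all(n_unique_B >= 0))
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# Reserved strips on chr1 kept clear of simulated variants, mask runs and
# excluded regions so plant_edge_cases() has deterministic space to work in.
edge_reserved_strips <- function(window_size = 3e6) {
  IRanges::IRanges(start = c(1L, as.integer(window_size - 100)),
                   end = c(1000L, as.integer(window_size + 100)))
}

# Place non-overlapping runs of exponential length until `target` bases are
# covered (last run trimmed so the total is exact). `forbidden` is an IRanges
# of strips the runs must avoid.
place_runs <- function(target, chrom_len, mean_len, min_len = 100L,
                       forbidden = NULL) {
  acc <- IRanges::IRanges()
  total <- 0
  tries <- 0L
  while (total < target) {
    tries <- tries + 1L
    if (tries > 50000L) stop("could not place runs: contig too crowded")
    len <- max(min_len, round(stats::rexp(1, 1 / mean_len)))
    if (total + len > target) len <- target - total
    if (len < 1) break
    start <- sample.int(chrom_len - len, 1L)
    cand <- IRanges::IRanges(start, width = len)
    if (length(acc) && IRanges::overlapsAny(cand, acc)) next
    if (!is.null(forbidden) && IRanges::overlapsAny(cand, forbidden)) next
    acc <- c(acc, cand)
    total <- total + len
  }
  acc[order(IRanges::start(acc))]
}

rgq <- function(n, cfg) {
  below <- stats::runif(n) < cfg$gq_below_fraction
  out <- numeric(n)
  out[below] <- round(stats::runif(sum(below), cfg$gq_below_range[1],
                                   cfg$gq_below_range[2]))
  out[!below] <- pmin(99, pmax(31, round(stats::rnorm(sum(!below),
                                                      cfg$gq_above_mean,
                                                      cfg$gq_above_sd))))
  out
}

rqual <- function(n, cfg) {
  below <- stats::runif(n) < cfg$qual_below_fraction
  out <- numeric(n)
  out[below] <- round(stats::runif(sum(below), 5, 30), 1)
  out[!below] <- round(stats::runif(sum(!below), 35, 95), 1)
  out
}

# Greedy guarded position sampler: draws from `draw()` until `n` positions at
# least `guard` bp from each other and from `existing` are found.
sample_guarded <- function(n, draw, existing, guard) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, n))
      stop("chromosome too short for requested variant count")
    p <- draw()
    if (length(existing) && min(abs(existing - p)) < guard) next
    if (length(out) && min(abs(out - p)) < guard) next
    out <- c(out, p)
  }
  out
}

effect_for <- function(impact, var_class, in_gene) {
  if (impact == "HIGH") {
    if (var_class == "INDEL") "frameshift_variant" else "stop_gained"
  } else if (impact == "MODERATE") {
    if (var_class == "INDEL") "conservative_inframe_insertion"
    else "missense_variant"
  } else if (impact == "LOW") {
    "synonymous_variant"
  } else {
    if (in_gene) "intron_variant" else "intergenic_region"
  }
}

# depth track for one contig: exact planted zero-coverage total, remaining
# positions piecewise-constant around `mean_depth`.
simulate_track <- function(chrom, len, mean_depth, zero_frac,
                           zero_mean_len = 1e5, seg_mean_len = 5e3) {
  target <- round(zero_frac * len)
  zero <- if (target > 0)
    place_runs(target, len, mean_len = zero_mean_len, min_len = 100L)
  else IRanges::IRanges()
  covered <- IRanges::gaps(zero, start = 1L, end = len)
  rows <- list()
  for (i in seq_along(zero))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = IRanges::start(zero)[i] - 1L,
      end = IRanges::end(zero)[i], depth = 0)
  for (i in seq_along(covered)) {
    s <- IRanges::start(covered)[i]; e <- IRanges::end(covered)[i]
    seg_len <- e - s + 1
    n_seg <- max(1L, round(seg_len / seg_mean_len))
    cuts <- if (n_seg > 1L)
      sort(sample.int(seg_len - 1L, n_seg - 1L)) else integer(0)
    bounds <- c(0L, cuts, seg_len)
    d <- pmax(1, round(stats::rnorm(n_seg, mean_depth, 6)))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = s - 1L + bounds[-length(bounds)],
      end = s - 1L + bounds[-1L], depth = d)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a truth-labelled substrain comparison dataset
#'
#' Writes, under `outdir`: `reference.fa` (soft-masked FASTA), `mask.bed`
#' (the lowercase runs as BED3), `small_variants.vcf` (joint two-sample
#' SNP/indel VCF with QUAL, GT, GQ, DP and ANN), `sv.vcf` (SV records with
#' SVTYPE/SVLEN and PASS or non-PASS FILTER), `depth_A.bedgraph` /
#' `depth_B.bedgraph`, `excluded.bed` (planted assembly-error regions) and
#' `truth.csv` (one row per emitted record with the intended category,
#' planted qualities and the category the default filters should assign).
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if absent).
#' @return list with the file `paths`, the `truth` data.frame, `genes`,
#'   `chrom_lengths`, `mask` ranges, and the `cfg` used.
#' @export
simulate_substrains <- function(cfg = simulation_config(), outdir) {
  set.seed(cfg$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chroms <- c(paste0("chr", seq_len(cfg$n_autosomes)), "chrY")
  L <- as.integer(cfg$chrom_length)
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)
  reserved <- edge_reserved_strips()

  ## gene model: evenly spread fixed-length genes with positional jitter
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    slot <- floor(L / (cfg$n_genes_per_chrom + 1))
    start <- pmax(2000, seq_len(cfg$n_genes_per_chrom) * slot -
                    round(stats::runif(cfg$n_genes_per_chrom, 0,
                                       slot - cfg$gene_length - 100)))
    data.frame(chrom = ch, start = start, end = start + cfg$gene_length - 1,
               gene = sprintf("G%s.%d", sub("^chr", "", ch),
                              seq_len(cfg$n_genes_per_chrom)),
               stringsAsFactors = FALSE)
  }))

  ## reference with planted soft-mask runs
  seqs <- list(); mask <- list()
  bases <- c("A", "C", "G", "T")
  for (ch in chroms) {
    v <- sample(bases, L, replace = TRUE)
    forb <- if (ch == "chr1") reserved else NULL
    runs <- place_runs(round(cfg$softmask_fraction * L), L, mean_len = 800,
                       forbidden = forb)
    for (i in seq_along(runs)) {
      idx <- IRanges::start(runs)[i]:IRanges::end(runs)[i]
      v[idx] <- tolower(v[idx])
    }
    mask[[ch]] <- runs
    seqs[[ch]] <- paste(v, collapse = "")
  }

  ## excluded (assembly-error) regions
  excl <- list()
  for (ch in chroms) {
    forb <- if (ch == "chr1") reserved else NULL
    excl[[ch]] <- place_runs(cfg$n_excluded_per_chrom * cfg$excluded_length,
                             L, mean_len = cfg$excluded_length,
                             min_len = cfg$excluded_length, forbidden = forb)
  }

  ## allocate variant counts to chromosomes (proportional to length)
  groups <- data.frame(
    category = rep(c("shared", "unique_A", "unique_B"), each = 3),
    var_class = rep(c("SNP", "INDEL", "SV"), 3),
    n = c(cfg$n_shared_snp, cfg$n_shared_indel, cfg$n_shared_sv,
          cfg$n_unique_A[["snp"]], cfg$n_unique_A[["indel"]],
          cfg$n_unique_A[["sv"]],
          cfg$n_unique_B[["snp"]], cfg$n_unique_B[["indel"]],
          cfg$n_unique_B[["sv"]]),
    stringsAsFactors = FALSE)
  probs <- rep(1 / length(chroms), length(chroms))
  alloc <- lapply(groups$n, function(n)
    if (n > 0) as.vector(stats::rmultinom(1, n, probs)) else
      rep(0L, length(chroms)))

  truth_rows <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    per_group <- vapply(alloc, `[`, numeric(1), ci)
    n_ch <- sum(per_group)
    if (n_ch == 0) next
    cat_v <- rep(groups$category, per_group)
    cls_v <- rep(groups$var_class, per_group)
    impact <- ifelse(cls_v == "SV", "MODIFIER",
                     sample(names(cfg$impact_mix), n_ch, replace = TRUE,
                            prob = cfg$impact_mix))
    g <- genes[genes$chrom == ch, , drop = FALSE]
    forb <- if (ch == "chr1") reserved else NULL
    in_forbidden <- function(p) !is.null(forb) &&
      IRanges::overlapsAny(IRanges::IRanges(p, p), forb)
    draw_genic <- function() {
      row <- g[sample.int(nrow(g), 1L), ]
      p <- row$start + sample.int(cfg$gene_length - 50L, 1L)
      if (in_forbidden(p)) draw_genic() else p
    }
    draw_any <- function() {
      p <- sample(100:(L - 3200), 1L)
      if (in_forbidden(p)) draw_any() else p
    }
    pos <- numeric(n_ch)
    genic <- impact %in% c("HIGH", "MODERATE", "LOW")
    pos[genic] <- sample_guarded(sum(genic), draw_genic, numeric(0),
                                 cfg$guard)
    pos[!genic] <- sample_guarded(sum(!genic), draw_any, pos[genic],
                                  cfg$guard)
    pos <- as.integer(pos)

    ref_at <- function(p, k = 1L) toupper(substring(seqs[[ch]], p, p + k - 1L))
    n <- n_ch
    ref <- character(n); alt <- character(n)
    sv_type <- rep(NA_character_, n); sv_len <- rep(NA_real_, n)
    ab <- integer(n)
    for (i in seq_len(n)) {
      if (cls_v[i] == "SNP") {
        ref[i] <- ref_at(pos[i])
        alt[i] <- sample(setdiff(bases, ref[i]), 1L)
        ab[i] <- 1L
      } else if (cls_v[i] == "INDEL") {
        k <- sample.int(12L, 1L)
        if (stats::runif(1) < 0.5) {            # insertion
          ref[i] <- ref_at(pos[i])
          alt[i] <- paste0(ref[i], paste(sample(bases, k, replace = TRUE),
                                         collapse = ""))
        } else {                                 # deletion
          ref[i] <- ref_at(pos[i], k + 1L)
          alt[i] <- substring(ref[i], 1L, 1L)
        }
        ab[i] <- k
      } else {                                   # SV
        st <- sample(c("DEL", "INS", "DUP", "INV"), 1L)
        # short-event-dominated size spectrum typical of long-read SV calls
        len <- min(10000L, 50L + round(stats::rexp(1, 1 / 270)))
        sv_type[i] <- st
        sv_len[i] <- if (st == "DEL") -len else len
        ref[i] <- ref_at(pos[i])
        alt[i] <- paste0("<", st, ">")
        ab[i] <- len
      }
    }

    is_sv <- cls_v == "SV"
    het_shared <- cat_v == "shared" &
      stats::runif(n) < cfg$shared_het_fraction
    carrier_hom <- stats::runif(n) < cfg$unique_hom_fraction
    gt_carrier <- ifelse(cat_v == "shared",
                         ifelse(het_shared, "0/1", "1/1"),
                         ifelse(carrier_hom, "1/1", "0/1"))
    gt_A <- ifelse(cat_v == "unique_B", "0/0", gt_carrier)
    gt_B <- ifelse(cat_v == "unique_A", "0/0", gt_carrier)
    gq_A <- ifelse(is_sv, NA_real_, rgq(n, cfg))
    gq_B <- ifelse(is_sv, NA_real_, rgq(n, cfg))
    dp_A <- pmax(1, round(stats::rnorm(n, cfg$depth_mean[["A"]], 6)))
    dp_B <- pmax(1, round(stats::rnorm(n, cfg$depth_mean[["B"]], 6)))
    qual <- ifelse(is_sv, NA_real_, rqual(n, cfg))
    filter <- ifelse(!is_sv, NA_character_,
                     ifelse(stats::runif(n) < cfg$sv_pass_fraction,
                            "PASS", "NearReferenceGap"))
    in_gene_flag <- vapply(pos, function(p)
      any(p >= g$start & p <= g$end), logical(1))
    gene_lab <- vapply(seq_len(n), function(i) {
      if (in_gene_flag[i]) g$gene[which(pos[i] >= g$start &
                                          pos[i] <= g$end)[1]]
      else g$gene[which.min(abs(g$start - pos[i]))]
    }, character(1))
    effect <- vapply(seq_len(n), function(i)
      effect_for(impact[i], cls_v[i], in_gene_flag[i]), character(1))
    ann <- sprintf("%s|%s|%s|%s|%s.t1",
                   vapply(strsplit(alt, ","), `[`, character(1), 1L),
                   effect, impact, gene_lab, gene_lab)

    truth_rows[[ch]] <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      var_class = cls_v, sv_type = sv_type, sv_len = sv_len,
      category = cat_v, gt_A = gt_A, gt_B = gt_B,
      gq_A = gq_A, gq_B = gq_B, dp_A = dp_A, dp_B = dp_B,
      qual = qual, filter = filter,
      impact = impact, effect = effect, gene = gene_lab, ann = ann,
      affected_bases = ab, edge = NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), var_class = character(), sv_type = character(),
      sv_len = numeric(), category = character(), gt_A = character(),
      gt_B = character(), gq_A = numeric(), gq_B = numeric(),
      dp_A = numeric(), dp_B = numeric(), qual = numeric(),
      filter = character(), impact = character(), effect = character(),
      gene = character(), ann = character(), affected_bases = integer(),
      edge = character(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  truth$masked <- is_masked(mask, truth$chrom, truth$pos)
  truth$in_excluded <- is_masked(excl, truth$chrom, truth$pos)
  truth <- finalize_truth(truth, cfg)

  sim <- list(truth = truth, genes = genes, chrom_lengths = chrom_lengths,
              mask = mask, excluded = excl, cfg = cfg, outdir = outdir,
              seqs = seqs)
  sim$paths <- write_sim_files(sim)
  sim$seqs <- NULL   # do not keep ~30 Mb of sequence in the returned object
  sim
}

# Expected classification under the default thresholds, given the planted
# values, plus marker-candidacy truth. Shared GQ is strict (>30); unique GQ
# is inclusive (>=30).
finalize_truth <- function(truth, cfg) {
  is_sv <- truth$var_class == "SV"
  missing_gt <- zygosity(truth$gt_A) == "missing" |
    zygosity(truth$gt_B) == "missing"
  gq_fail <- !is_sv & (
    (truth$category == "shared" &
       (is.na(truth$gq_A) | is.na(truth$gq_B) |
          truth$gq_A <= 30 | truth$gq_B <= 30)) |
    (truth$category %in% c("unique_A", "unique_B") &
       (is.na(truth$gq_A) | is.na(truth$gq_B) |
          truth$gq_A < 30 | truth$gq_B < 30)))
  qual_fail <- !is_sv & (is.na(truth$qual) | truth$qual <= 30)
  sv_fail <- is_sv & truth$filter != "PASS"
  discard <- truth$in_excluded | qual_fail | sv_fail | missing_gt | gq_fail
  truth$expected_category <- ifelse(discard, "discarded", truth$category)
  truth$is_marker_candidate <- truth$expected_category %in%
    c("unique_A", "unique_B") & truth$var_class == "SNP" &
    ((norm_gt(truth$gt_A) == "1/1" & norm_gt(truth$gt_B) == "0/0") |
       (norm_gt(truth$gt_A) == "0/0" & norm_gt(truth$gt_B) == "1/1")) &
    !is.na(truth$gq_A) & !is.na(truth$gq_B) &
    truth$gq_A >= 30 & truth$gq_B >= 30 & !truth$masked
  truth
}

truth_to_variant_table <- function(truth, cfg) {
  df <- truth[, c("chrom", "pos", "ref", "alt", "qual", "filter",
                  "var_class", "sv_type", "sv_len", "gt_A", "gt_B",
                  "gq_A", "gq_B", "dp_A", "dp_B", "ann")]
  new_variant_table(df, cfg$sample_names)
}

write_sim_files <- function(sim) {
  cfg <- sim$cfg; outdir <- sim$outdir; truth <- sim$truth
  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    mask_bed = file.path(outdir, "mask.bed"),
    small_vcf = file.path(outdir, "small_variants.vcf"),
    sv_vcf = file.path(outdir, "sv.vcf"),
    depth_A = file.path(outdir, "depth_A.bedgraph"),
    depth_B = file.path(outdir, "depth_B.bedgraph"),
    excluded_bed = file.path(outdir, "excluded.bed"),
    truth = file.path(outdir, "truth.csv"))
  if (!is.null(sim$seqs)) {
    write_reference_fasta(sim$seqs, paths$reference)
    write_mask_bed(sim$mask, paths$mask_bed)
    write_mask_bed(sim$excluded, paths$excluded_bed)
    for (s in c("A", "B")) {
      zf <- ifelse(names(sim$chrom_lengths) == "chrY", cfg$zero_frac_y,
                   cfg$zero_frac_autosome)
      tr <- do.call(rbind, lapply(seq_along(sim$chrom_lengths), function(i)
        simulate_track(names(sim$chrom_lengths)[i], sim$chrom_lengths[[i]],
                       cfg$depth_mean[[s]], zf[i])))
      write_depth_track(tr, paths[[paste0("depth_", s)]])
    }
  }
  tab <- truth_to_variant_table(truth, cfg)
  small <- tab[tab$var_class != "SV", , drop = FALSE]
  sv <- tab[tab$var_class == "SV", , drop = FALSE]
  attr(small, "samples") <- cfg$sample_names
  attr(sv, "samples") <- cfg$sample_names
  class(small) <- class(sv) <- c("variant_table", "data.frame")
  write_variant_vcf(small, paths$small_vcf, contigs = sim$chrom_lengths)
  write_variant_vcf(sv, paths$sv_vcf, contigs = sim$chrom_lengths)
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  paths
}

#' Plant guaranteed edge cases into a simulated dataset
#'
#' Appends, on chr1 (in coordinate strips the generator keeps clear), one
#' record for each boundary the classification and marker rules must handle:
#' GQ exactly 30 on a shared variant (strict threshold: discarded) and on a
#' unique hom-discordant variant (inclusive threshold: kept, and a marker
#' candidate), QUAL exactly 30 (discarded), a shared 0/1-0/1 heterozygote, a
#' 1/1 vs 1/2 discordant pair, a homozygous-discordant SNP inside a
#' soft-masked run (unique but never a marker candidate), a non-PASS SV, a
#' missing ./. genotype, and homozygous-discordant SNPs at the marker-window
#' boundary positions `window_size` and `window_size + 1`. VCFs and truth
#' table are rewritten in sorted order.
#'
#' @param sim result of [simulate_substrains()].
#' @param window_size marker window size whose boundary is exercised.
#' @return the updated simulation list (truth rows carry an `edge` label).
#' @export
plant_edge_cases <- function(sim, window_size = 3e6) {
  cfg <- sim$cfg
  base <- function(chrom, pos, ...) {
    row <- list(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
                var_class = "SNP", sv_type = NA_character_, sv_len = NA_real_,
                category = "shared", gt_A = "1/1", gt_B = "1/1",
                gq_A = 60, gq_B = 60, dp_A = 40, dp_B = 40,
                qual = 50, filter = NA_character_,
                impact = "MODIFIER", effect = "intergenic_region",
                gene = "G1.1", ann = NA_character_,
                affected_bases = 1L, edge = NA_character_,
                masked = FALSE, in_excluded = FALSE)
    mods <- list(...)
    row[names(mods)] <- mods
    row$ann <- sprintf("%s|%s|%s|%s|%s.t1",
                       strsplit(row$alt, ",")[[1]][1], row$effect,
                       row$impact, row$gene, row$gene)
    row
  }
  # a masked chr1 position clear of existing variants
  chr1_pos <- sim$truth$pos[sim$truth$chrom == "chr1"]
  mask1 <- sim$mask[["chr1"]]
  masked_pos <- NA_integer_
  for (i in seq_along(mask1)) {
    cand <- IRanges::start(mask1)[i] +
      floor(IRanges::width(mask1)[i] / 2)
    if (!length(chr1_pos) || min(abs(chr1_pos - cand)) >= cfg$guard) {
      masked_pos <- cand; break
    }
  }
  if (is.na(masked_pos)) stop("no free masked position on chr1")

  rows <- list(
    base("chr1", 101, edge = "gq_at_threshold_shared", gq_A = 30, gq_B = 30),
    base("chr1", 151, edge = "gq_at_threshold_unique", category = "unique_A",
         gt_B = "0/0", gq_A = 30, gq_B = 30),
    base("chr1", 201, edge = "qual_at_threshold", qual = 30),
    base("chr1", 251, edge = "shared_het", gt_A = "0/1", gt_B = "0/1"),
    base("chr1", 301, edge = "discordant_other", alt = "T,G",
         gt_A = "1/1", gt_B = "1/2", category = "discordant_other"),
    base("chr1", masked_pos, edge = "masked_unique_snp",
         category = "unique_A", gt_B = "0/0", masked = TRUE),
    base("chr1", 401, edge = "nonpass_sv", var_class = "SV",
         sv_type = "DEL", sv_len = -300, alt = "<DEL>",
         qual = NA_real_, gq_A = NA_real_, gq_B = NA_real_,
         filter = "NearReferenceGap", affected_bases = 300L),
    base("chr1", 451, edge = "missing_genotype", gt_A = "./.",
         gt_B = "0/1", category = "discarded"),
    base("chr1", window_size, edge = "window_boundary_lo",
         category = "unique_A", gt_B = "0/0", gq_A = 55, gq_B = 50),
    base("chr1", window_size + 1, edge = "window_boundary_hi",
         category = "unique_B", gt_A = "0/0", gt_B = "1/1",
         gq_A = 55, gq_B = 50))
  add <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  add <- finalize_truth(add, cfg)
  truth <- rbind(sim$truth, add)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  stopifnot(!anyDuplicated(paste(truth$chrom, truth$pos)))
  sim$truth <- truth
  # rewrite the VCFs and truth csv (reference/mask/depth are unchanged)
  tab <- truth_to_variant_table(truth, cfg)
  small <- tab[tab$var_class != "SV", , drop = FALSE]
  sv <- tab[tab$var_class == "SV", , drop = FALSE]
  attr(small, "samples") <- cfg$sample_names
  attr(sv, "samples") <- cfg$sample_names
  class(small) <- class(sv) <- c("variant_table", "data.frame")
  write_variant_vcf(small, sim$paths$small_vcf, contigs = sim$chrom_lengths)
  write_variant_vcf(sv, sim$paths$sv_vcf, contigs = sim$chrom_lengths)
  utils::write.csv(truth, sim$paths$truth, row.names = FALSE)
  sim
}
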
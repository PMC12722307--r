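# Shared fixtures and independent oracles, all built in code at test time.

# Build a variant_table row by row without going through a file.
rec <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T", qual = 50,
                filter = NA_character_, var_class = "SNP",
                sv_type = NA_character_, sv_len = NA_real_,
                gt_A = "1/1", gt_B = "1/1", gq_A = 60, gq_B = 60,
                dp_A = 40, dp_B = 40, ann = NA_character_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             filter = filter, var_class = var_class, sv_type = sv_type,
             sv_len = sv_len, gt_A = gt_A, gt_B = gt_B, gq_A = gq_A,
             gq_B = gq_B, dp_A = dp_A, dp_B = dp_B, ann = ann,
             stringsAsFactors = FALSE)
}

vt <- function(..., samples = c(A = "S1", B = "S2")) {
  substrainr:::new_variant_table(do.call(rbind, list(...)), samples)
}

# One default-condition simulated dataset (with planted edge cases), built
# once per test session and reused across files.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "substrainr_default_sim")
      cache <<- plant_edge_cases(
        simulate_substrains(simulation_config(seed = 101L), outdir = dir))
    }
    cache
  }
})

# Classify a simulated dataset's VCFs with the default thresholds and its
# planted excluded regions; returns rows aligned with sim$truth.
classify_sim <- function(sim) {
  cfg <- sim$cfg
  v <- rbind(read_joint_vcf(sim$paths$small_vcf, cfg$sample_names),
             read_sv_vcf(sim$paths$sv_vcf, cfg$sample_names))
  attr(v, "samples") <- cfg$sample_names
  class(v) <- c("variant_table", "data.frame")
  cl <- classify_variants(
    v, classification_config(
      excluded_regions = mask_from_bed(sim$paths$excluded_bed)))
  cl[match(paste(sim$truth$chrom, sim$truth$pos),
           paste(cl$chrom, cl$pos)), ]
}

# Per-base brute-force coverage oracle (independent of the interval-weighted
# implementation path).
coverage_oracle <- function(track, low_max = 10, medium_max = 30) {
  d <- rep(track$depth, track$end - track$start)
  L <- length(d)
  s <- sort(d)
  med <- s[if (L %% 2 == 0) L / 2 else (L + 1) / 2]
  list(mean = mean(d), median = med, min = min(d), max = max(d),
       sd = sqrt(mean((d - mean(d))^2)),
       pct_zero = 100 * mean(d == 0),
       pct_low = 100 * mean(d > 0 & d <= low_max),
       pct_medium = 100 * mean(d > low_max & d <= medium_max),
       pct_high = 100 * mean(d > medium_max))
}

# Brute-force per-window arg-max oracle for marker selection: filter/compare
# steps, not a sort, so it is independent of select_panel's order/duplicated
# path.
panel_oracle <- function(candidates) {
  groups <- split(candidates, paste(candidates$chrom, candidates$window_index))
  picks <- lapply(groups, function(g) {
    g <- g[g$avg_gq == max(g$avg_gq), , drop = FALSE]
    g <- g[g$min_gq == max(g$min_gq), , drop = FALSE]
    g[g$pos == min(g$pos), , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random candidate-marker fixture for the oracle-equivalence property.
random_candidates <- function(n, n_chrom = 5, chrom_len = 12e6,
                              window_size = 3e6) {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sample.int(chrom_len, sum(sel))
  }
  gq_A <- round(stats::runif(n, 30, 99))
  gq_B <- round(stats::runif(n, 30, 99))
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             category = sample(c("unique_A", "unique_B"), n, replace = TRUE),
             genotype_A = "1/1", genotype_B = "0/0",
             gq_A = gq_A, gq_B = gq_B,
             avg_gq = (gq_A + gq_B) / 2, min_gq = pmin(gq_A, gq_B),
             window_index = as.integer(floor((pos - 1) / window_size)),
             stringsAsFactors = FALSE)
}

# Random joint-call fixture exercising every genotype combination, for the
# partition/symmetry/monotonicity properties.
random_variant_fixture <- function(n = 400) {
  gts <- c("0/0", "0/1", "1/1", "1/2", "./.")
  cls <- sample(c("SNP", "INDEL", "SV"), n, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
  is_sv <- cls == "SV"
  df <- rec(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
            pos = sample.int(1e6, n), ref = "A",
            alt = ifelse(is_sv, "<DEL>", "T,G"),
            qual = ifelse(is_sv, NA_real_, round(stats::runif(n, 0, 99), 1)),
            filter = ifelse(is_sv,
                            sample(c("PASS", "NearReferenceGap"), n, TRUE),
                            NA_character_),
            var_class = cls,
            sv_type = ifelse(is_sv, "DEL", NA_character_),
            sv_len = ifelse(is_sv, -200, NA_real_),
            gt_A = sample(gts, n, replace = TRUE),
            gt_B = sample(gts, n, replace = TRUE),
            gq_A = ifelse(is_sv, NA_real_, round(stats::runif(n, 0, 99))),
            gq_B = ifelse(is_sv, NA_real_, round(stats::runif(n, 0, 99))))
  substrainr:::new_variant_table(df, c(A = "S1", B = "S2"))
}

# Swap the two sample columns of a variant table.
swap_samples <- function(x) {
  sw <- x
  sw$gt_A <- x$gt_B; sw$gt_B <- x$gt_A
  sw$gq_A <- x$gq_B; sw$gq_B <- x$gq_A
  sw$dp_A <- x$dp_B; sw$dp_B <- x$dp_A
  sw
}
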
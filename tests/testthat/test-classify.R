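test_that("site filters: QUAL boundary, SV PASS rule, excluded regions, order", {
  cfg <- classification_config()
  x <- vt(rec(pos = 10L, qual = 29.9),
          rec(pos = 20L, qual = 30),
          rec(pos = 30L, qual = 30.1),
          rec(pos = 40L, var_class = "SV", sv_type = "DEL", sv_len = -100,
              alt = "<DEL>", qual = 1, filter = "PASS"),
          rec(pos = 50L, var_class = "SV", sv_type = "DEL", sv_len = -100,
              alt = "<DEL>", qual = 99, filter = "NearReferenceGap"))
  qc <- apply_quality_filters(x, cfg)
  expect_equal(qc$qc_pass, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(qc$qc_reason, c("qual", "qual", NA, NA, "filter"))
  # excluded region outranks qual in the reported reason
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5\t25", bed)
  cfg2 <- classification_config(excluded_regions = mask_from_bed(bed))
  qc2 <- apply_quality_filters(x, cfg2)
  expect_equal(qc2$qc_reason[1:2], c("excluded_region", "excluded_region"))
  expect_equal(qc2$qc_reason[3:5], qc$qc_reason[3:5])
})

test_that("classification implements the shared/unique/discordant rules", {
  x <- vt(rec(pos = 10L, gt_A = "1/1", gt_B = "1/1", gq_A = 60, gq_B = 61),
          rec(pos = 20L, gt_A = "1/1", gt_B = "0/0", gq_A = 50, gq_B = 50),
          rec(pos = 30L, gt_A = "0/1", gt_B = "0/1", gq_A = 45, gq_B = 45),
          rec(pos = 40L, alt = "T,G", gt_A = "1/1", gt_B = "1/2"),
          rec(pos = 50L, gt_A = "./.", gt_B = "0/1"),
          rec(pos = 60L, gt_A = "0/0", gt_B = "1/1", gq_A = 30, gq_B = 30),
          rec(pos = 70L, gt_A = "0/1", gt_B = "0/1", gq_A = 30, gq_B = 45),
          rec(pos = 80L, gt_A = "1/0", gt_B = "0/1"),
          rec(pos = 90L, gt_A = "0/0", gt_B = "0/0"))
  cl <- classify_variants(x)
  expect_equal(cl$category,
               c("shared", "unique_A", "shared", "discordant_other",
                 "discarded", "unique_B", "discarded", "shared",
                 "discarded"))
  expect_equal(cl$discard_reason[c(5, 7, 9)],
               c("missing_genotype", "low_gq", "hom_ref_both"))
  expect_equal(cl$hom[c(1, 3)], c(TRUE, FALSE))
  # GQ boundary: exactly 30 fails the strict shared rule (row 7) but passes
  # the inclusive unique rule (row 6)
  expect_equal(cl$category[6], "unique_B")
  # SVs: FILTER=PASS replaces the GQ requirement
  sv <- vt(rec(pos = 10L, var_class = "SV", sv_type = "INS", sv_len = 300,
               alt = "<INS>", qual = NA_real_, filter = "PASS",
               gq_A = NA_real_, gq_B = NA_real_),
           rec(pos = 50L, var_class = "SV", sv_type = "INS", sv_len = 300,
               alt = "<INS>", qual = NA_real_, filter = "NearReferenceGap",
               gq_A = NA_real_, gq_B = NA_real_, gt_A = "1/1", gt_B = "0/0"))
  svc <- classify_variants(sv)
  expect_equal(svc$category, c("shared", "discarded"))
  expect_equal(svc$discard_reason[2], "filter")
})

test_that("affected bases: SNP=1, indel=length difference, SV=|SVLEN|", {
  x <- vt(rec(pos = 10L),
          rec(pos = 20L, ref = "A", alt = "ATTT", var_class = "INDEL"),
          rec(pos = 30L, ref = "ACGTT", alt = "A", var_class = "INDEL"),
          rec(pos = 40L, ref = "A", alt = "AT,ATTTTT", var_class = "INDEL",
              gt_A = "1/2", gt_B = "1/1"),
          rec(pos = 50L, var_class = "SV", sv_type = "DEL", sv_len = -500,
              alt = "<DEL>", filter = "PASS"),
          rec(pos = 60L, var_class = "SV", sv_type = "BND", sv_len = NA_real_,
              alt = "<BND>", filter = "PASS"))
  expect_warning(ab <- affected_bases(x), "without resolvable length")
  expect_equal(ab, c(1L, 3L, 4L, 5L, 500L, 1L))
  # only the called alt counts for multi-allelics
  y <- vt(rec(pos = 40L, ref = "A", alt = "AT,ATTTTT", var_class = "INDEL",
              gt_A = "0/1", gt_B = "1/1"))
  expect_equal(affected_bases(y), 1L)
})

test_that("per-chromosome summary applies the homozygosity formula", {
  x <- vt(rec(pos = 10L), rec(pos = 20L), rec(pos = 30L),
          rec(pos = 40L, gt_A = "0/1", gt_B = "0/1", gq_A = 50, gq_B = 45),
          rec(chrom = "chr2", pos = 10L, gt_A = "1/1", gt_B = "0/0",
              gq_A = 40, gq_B = 50))
  s <- summarize_by_chrom(classify_variants(x))
  shared1 <- s[s$chrom == "chr1" & s$category == "shared", ]
  expect_equal(shared1$n, 4L)
  expect_equal(shared1$homozygous_pct, 75.0)      # 3 of 4 homozygous
  expect_equal(shared1$mean_gq_A, (60 * 3 + 50) / 4)
  expect_equal(shared1$mean_gq_B, (60 * 3 + 45) / 4)
  u2 <- s[s$chrom == "chr2", ]
  expect_equal(u2$category, "unique_A")
  expect_equal(u2$homozygous_pct, 100)
  expect_equal(u2$mean_gq_B, 50)
  # chromosomes with nothing kept simply do not appear
  expect_false("chr3" %in% s$chrom)
})

test_that("totals: divergent sites/bases and heterozygous share", {
  x <- vt(rec(pos = 10L),                                     # shared hom
          rec(pos = 20L, gt_A = "0/1", gt_B = "0/1"),          # shared het
          rec(pos = 30L, gt_A = "1/1", gt_B = "0/0"),          # unique_A SNP
          rec(pos = 40L, ref = "A", alt = "ATTT", var_class = "INDEL",
              gt_A = "0/0", gt_B = "1/1"),                     # unique_B
          rec(pos = 50L, var_class = "SV", sv_type = "DEL", sv_len = -500,
              alt = "<DEL>", filter = "PASS", gt_A = "1/1", gt_B = "0/0"))
  tot <- variant_totals(classify_variants(x), genome_length = 1e6)
  expect_equal(tot$divergent_sites, 3L)
  expect_equal(tot$divergent_bases, 1L + 3L + 500L)
  expect_equal(tot$sv_base_pct, 100 * 500 / 504)
  expect_equal(tot$shared_het_fraction, 0.5)
  expect_equal(tot$het_genome_pct, 100 * 1 / 1e6)
  empty <- variant_totals(classify_variants(vt(rec())[0, ]))
  expect_equal(empty$divergent_sites, 0L)
  expect_equal(empty$divergent_bases, 0L)
})

test_that("partition: every record lands in exactly one category", {
  set.seed(21)
  for (i in 1:10) {
    x <- random_variant_fixture(300)
    cl <- classify_variants(x)
    expect_equal(sum(table(cl$category)), nrow(x))
    expect_true(all(cl$category %in% c("shared", "unique_A", "unique_B",
                                       "discordant_other", "discarded")))
    expect_true(all(!is.na(cl$discard_reason[cl$category == "discarded"])))
  }
})

test_that("symmetry: swapping samples swaps unique_A and unique_B exactly", {
  set.seed(22)
  for (i in 1:10) {
    x <- random_variant_fixture(300)
    a <- table(factor(classify_variants(x)$category, levels = substrainr:::CATEGORIES))
    b <- table(factor(classify_variants(swap_samples(x))$category,
                      levels = substrainr:::CATEGORIES))
    expect_equal(unname(a[["unique_A"]]), unname(b[["unique_B"]]))
    expect_equal(unname(a[["unique_B"]]), unname(b[["unique_A"]]))
    expect_equal(unname(a[["shared"]]), unname(b[["shared"]]))
    expect_equal(unname(a[["discordant_other"]]),
                 unname(b[["discordant_other"]]))
  }
})

test_that("raising GQ thresholds can only shrink shared and unique sets", {
  set.seed(23)
  x <- random_variant_fixture(500)
  sizes <- vapply(c(0, 20, 40, 60, 80), function(g) {
    cl <- classify_variants(x, classification_config(gq_min_shared = g,
                                                     gq_min_unique = g))
    sum(cl$category %in% c("shared", "unique_A", "unique_B"))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("classification recovers the generator's truth labels", {
  sim <- default_sim()
  cl <- classify_sim(sim)
  expect_equal(nrow(cl), nrow(sim$truth))
  expect_equal(cl$category, sim$truth$expected_category)
  # planted sub-threshold records are exactly the discarded ones
  planted_bad <- sim$truth$expected_category == "discarded"
  expect_equal(cl$category == "discarded", planted_bad)
  # per-chromosome counts match the truth table
  s <- summarize_by_chrom(cl)
  for (ch in unique(sim$truth$chrom)) {
    tr <- sim$truth[sim$truth$chrom == ch, ]
    expect_equal(sum(s$n[s$chrom == ch & s$category == "shared"]),
                 sum(tr$expected_category == "shared"), info = ch)
  }
  # divergent totals equal the truth sums
  tot <- variant_totals(cl)
  uniq <- sim$truth$expected_category %in% c("unique_A", "unique_B")
  expect_equal(tot$divergent_sites, sum(uniq))
  expect_equal(tot$divergent_bases, sum(sim$truth$affected_bases[uniq]))
})
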
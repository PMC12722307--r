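test_that("zygosity covers the four states and tolerates phase/haploidy", {
  expect_equal(zygosity(c("0/0", "1/1", "0/1", "1|0", "./.", ".", NA, "2/2",
                          "1")),
               c("hom_ref", "hom_alt", "het", "het", "missing", "missing",
                 "missing", "hom_alt", "hom_alt"))
})

test_that("joint VCF reader maps genotypes, classes and ANN faithfully", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="a">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t5\t.\tA\tT\t45.2\t.\tANN=T|missense_variant|MODERATE|Wwc1|tx1\tGT:GQ\t1/1:60\t1/1:60",
    "chr1\t9\t.\tG\tC\t31\t.\t.\tGT:GQ\t./.:.\t0/1:20",
    "chr1\t20\t.\tA\tATTT\t50\t.\t.\tGT:GQ\t1/1:55\t0/0:44",
    "chr1\t30\t.\tA\tT,G\t50\t.\t.\tGT:GQ\t1/1:55\t1/2:44"),
    path)
  v <- read_joint_vcf(path, c(A = "S1", B = "S2"))
  expect_equal(nrow(v), 4L)
  expect_equal(v$var_class, c("SNP", "SNP", "INDEL", "SNP"))
  expect_equal(zygosity(v$gt_A), c("hom_alt", "missing", "hom_alt",
                                   "hom_alt"))
  expect_equal(v$gq_A, c(60, NA, 55, 55))
  expect_equal(v$qual[1], 45.2)
  expect_equal(v$ann[1], "T|missense_variant|MODERATE|Wwc1|tx1")
  expect_equal(v$alt[4], "T,G")  # multi-allelic kept unsplit
  # sample identity comes from configuration, not column order
  v2 <- read_joint_vcf(path, c(A = "S2", B = "S1"))
  expect_equal(v2$gt_A, v$gt_B)
  expect_error(read_joint_vcf(path, c(A = "S1", B = "nope")),
               "not present")
})

test_that("malformed genotypes are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t5\t.\tA\tT\t50\t.\t.\tGT\t1/1\t0/0",
    "chr1\t9\t.\tG\tC\t50\t.\t.\tGT\tx/y\t0/0"), path)
  expect_warning(v <- read_joint_vcf(path, c(A = "S1", B = "S2")),
                 "malformed GT")
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "skipped"), 1L)
})

test_that("SV reader preserves FILTER, takes SVLEN with fallback, skips missing SVTYPE", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-500\tGT\t1/1\t1/1",
    "chr1\t900\t.\tA\tATTTTT\t.\tNearReferenceGap\tSVTYPE=INS\tGT\t0/1\t0/0",
    "chr1\t2000\t.\tA\tT\t.\tPASS\t.\tGT\t1/1\t1/1"), path)
  expect_warning(v <- read_sv_vcf(path, c(A = "S1", B = "S2")),
                 "lacking SVTYPE")
  expect_equal(nrow(v), 2L)
  expect_true(all(v$var_class == "SV"))
  expect_equal(v$sv_len, c(-500, 5))   # SVLEN, then allele-length fallback
  expect_equal(v$filter, c("PASS", "NearReferenceGap"))
})

test_that("ANN parsing, severity vocabulary and round trip", {
  e <- parse_ann("A|missense_variant|MODERATE|Wwc1|tx1")
  expect_equal(nrow(e), 1L)
  expect_equal(e$impact, "MODERATE")
  expect_equal(e$gene, "Wwc1")
  expect_equal(nrow(parse_ann(NA_character_)), 0L)
  expect_equal(nrow(parse_ann("")), 0L)
  two <- parse_ann(paste0("T|stop_gained|HIGH|G1|t1,",
                          "T|intron_variant|MODIFIER|G2|t2"))
  expect_equal(two$impact, c("HIGH", "MODIFIER"))   # order preserved
  short <- parse_ann("T|missense,T|synonymous_variant|LOW|G1|t1")
  expect_equal(attr(short, "rejected"), 1L)
  expect_equal(nrow(short), 1L)
  expect_error(parse_ann("T|x|SEVERE|G|t"), "unknown ANN impact")
  s <- "T|stop_gained|HIGH|G1|t1,A|intron_variant|MODIFIER|G2|t2"
  expect_identical(format_ann(parse_ann(s)), s)
})

test_that("VCF write -> read round trip preserves every modelled field", {
  x <- vt(
    rec(pos = 10L, qual = 45.2, ann = "T|missense_variant|MODERATE|Wwc1|t1"),
    rec(pos = 20L, ref = "G", alt = "GAA", var_class = "INDEL", gt_A = "0/1",
        gq_A = 31, qual = 88),
    rec(pos = 30L, gt_A = "./.", gq_A = NA_real_, qual = 31),
    rec(chrom = "chr2", pos = 40L, alt = "<DEL>", var_class = "SV",
        sv_type = "DEL", sv_len = -500, qual = NA_real_, filter = "PASS",
        gq_A = NA_real_, gq_B = NA_real_))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(x, path)
  y <- read_joint_vcf(path, attr(x, "samples"))
  for (col in c("chrom", "pos", "ref", "alt", "qual", "filter", "gt_A",
                "gt_B", "gq_A", "gq_B", "dp_A", "dp_B", "ann", "sv_type",
                "sv_len"))
    expect_equal(y[[col]], x[[col]], info = col)
  # a second write of the re-read table is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(y, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("soft-mask from FASTA and from equivalent BED answer identically", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTacgtACGT"), fa)
  ref <- read_masked_reference(fa)
  mask <- softmask_ranges(ref)
  expect_equal(which(is_masked(mask, rep("chr1", 12), 1:12)), 5:8)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t4\t8", bed)
  mask_bed <- mask_from_bed(bed)
  expect_equal(is_masked(mask_bed, rep("chr1", 12), 1:12),
               is_masked(mask, rep("chr1", 12), 1:12))
  expect_error(mask_from_bed({
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t8\t4", p); p
  }), "start >= end")
})

test_that("mask lookup matches a per-base case scan on a random sequence", {
  set.seed(42)
  n <- 10000L
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  for (i in 1:20) {  # plant lowercase runs
    s <- sample.int(n - 60L, 1L)
    idx <- s:(s + sample(5:60, 1L))
    chars[idx] <- tolower(chars[idx])
  }
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", paste(chars, collapse = "")), fa)
  mask <- softmask_ranges(read_masked_reference(fa))
  expect_equal(is_masked(mask, rep("c1", n), seq_len(n)),
               chars %in% letters)
})

test_that("coordinate conversions are inverse bijections on boundaries", {
  expect_equal(pos1_to_pos0(1L), 0L)
  expect_equal(pos0_to_pos1(0L), 1L)
  p <- c(1L, 2L, 100L, 3000000L)
  expect_equal(pos0_to_pos1(pos1_to_pos0(p)), p)
  r <- bed_to_ranges(c(0L, 4L), c(4L, 8L))
  expect_equal(IRanges::start(r), c(1L, 5L))
  expect_equal(IRanges::end(r), c(4L, 8L))
  b <- ranges_to_bed(r)
  expect_equal(b$start, c(0L, 4L))
  expect_equal(b$end, c(4L, 8L))
  expect_error(bed_to_ranges(4L, 4L), "start >= end")
})

test_that("depth-track tiling invariant is enforced", {
  good <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 250),
                     depth = c(5, 0))
  expect_silent(validate_depth_track(good, c(c1 = 250)))
  expect_error(validate_depth_track(
    data.frame(chrom = "c1", start = c(0, 120), end = c(100, 250),
               depth = c(5, 0))), "gaps")
  expect_error(validate_depth_track(good, c(c1 = 300)), "full contig")
  expect_error(validate_depth_track(good[0, ]), "empty")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_depth_track(good, p)
  expect_equal(read_depth_track(p), good)
})
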
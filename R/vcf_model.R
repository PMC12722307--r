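# Data model and I/O for the VCF dialects, reference FASTA, depth tracks and
# interval masks used throughout the package.
#
# Internal conventions:
#   * variant tables are plain data.frames (class "variant_table") with one
#     row per VCF record; the two samples are always column-suffixed _A/_B
#     and the original sample names live in attr(x, "samples").
#   * interval sets are named lists of IRanges (1-based, closed), the
#     Bioconductor convention; BED input/output converts at the boundary.
#   * VCF POS is 1-based throughout, as in the format itself.

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Zygosity of a VCF genotype string
#'
#' Classifies diploid (or haploid) GT strings into the four zygosity states
#' used by the classification rules. Any missing allele (`.`) makes the whole
#' call missing; phased separators are accepted.
#'
#' @param gt character vector of GT strings (e.g. "0/1", "1|1", "./.").
#' @return character vector with values "hom_ref", "hom_alt", "het" or
#'   "missing".
#' @examples
#' zygosity(c("1/1", "0/0", "0/1", "./.", "1/2"))
#' @export
zygosity <- function(gt) {
  out <- rep("missing", length(gt))
  ok <- !is.na(gt)
  gt2 <- as.character(gt); gt2[!ok] <- "."
  parts <- strsplit(gt2, "[/|]")
  for (i in which(ok)) {
    a <- parts[[i]]
    if (any(a == ".") || length(a) < 1L || length(a) > 2L ||
        anyNA(suppressWarnings(as.integer(a)))) next
    ai <- as.integer(a)
    if (length(ai) == 1L) ai <- c(ai, ai)
    if (all(ai == 0L)) out[i] <- "hom_ref"
    else if (ai[1] == ai[2]) out[i] <- "hom_alt"
    else out[i] <- "het"
  }
  out
}

# Normalise a GT string to sorted allele indices ("1/0" -> "0/1") so genotype
# identity ignores allele order and phasing. Missing stays NA.
norm_gt <- function(gt) {
  gt2 <- as.character(gt); gt2[is.na(gt2)] <- "."
  parts <- strsplit(gt2, "[/|]")
  vapply(parts, function(a) {
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || length(ai) < 1L) return(NA_character_)
    if (length(ai) == 1L) ai <- c(ai, ai)
    paste(sort(ai), collapse = "/")
  }, character(1))
}

gt_is_valid <- function(gt) {
  grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)
}

# Allele indices (>0) actually called in either sample; integer(0) if none.
called_alt_indices <- function(gt_a, gt_b) {
  a <- suppressWarnings(as.integer(unlist(strsplit(c(gt_a, gt_b), "[/|]"))))
  a <- a[!is.na(a) & a > 0L]
  sort(unique(a))
}

## ---- SnpEff ANN field --------------------------------------------------

#' Parse a SnpEff ANN INFO value
#'
#' Splits the comma-separated ANN value into entries and each entry on pipes,
#' keeping the five leading subfields the pipeline uses (allele, effect,
#' impact, gene symbol, transcript/feature id). Entries with fewer than four
#' pipe-delimited fields are dropped and counted in the "rejected" attribute.
#'
#' @param ann a single raw ANN string (no leading "ANN="), or NA/"" for none.
#' @return data.frame with columns allele, effect, impact, gene, transcript;
#'   zero rows for empty input. Attribute "rejected" counts dropped entries.
#' @examples
#' parse_ann("A|missense_variant|MODERATE|Wwc1|tx1")
#' @export
parse_ann <- function(ann) {
  empty <- data.frame(allele = character(), effect = character(),
                      impact = character(), gene = character(),
                      transcript = character(), stringsAsFactors = FALSE)
  if (length(ann) != 1L) stop("parse_ann() takes a single ANN string")
  if (is.na(ann) || !nzchar(ann)) {
    attr(empty, "rejected") <- 0L
    return(empty)
  }
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 4L
  rejected <- sum(!ok)
  fields <- fields[ok]
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else "", character(1))
  out <- data.frame(allele = get(1), effect = get(2), impact = get(3),
                    gene = get(4), transcript = get(5),
                    stringsAsFactors = FALSE)
  bad <- !out$impact %in% IMPACT_LEVELS
  if (any(bad)) stop("unknown ANN impact value(s): ",
                     paste(unique(out$impact[bad]), collapse = ", "))
  attr(out, "rejected") <- rejected
  out
}

#' Format ANN entries back to the raw INFO value
#'
#' Inverse of [parse_ann()] on the five subfields this package retains.
#'
#' @param entries data.frame as returned by [parse_ann()].
#' @return single character string, or NA_character_ for zero entries.
#' @export
format_ann <- function(entries) {
  if (nrow(entries) == 0L) return(NA_character_)
  paste(apply(entries[, c("allele", "effect", "impact", "gene", "transcript")],
              1L, paste, collapse = "|"), collapse = ",")
}

## ---- coordinate conversion ---------------------------------------------

#' Convert between 1-based VCF positions and 0-based offsets
#'
#' `pos1_to_pos0()` and `pos0_to_pos1()` are inverse bijections between the
#' 1-based coordinates VCF uses and 0-based offsets (BED start convention).
#' `bed_to_ranges()` turns 0-based half-open BED intervals into the 1-based
#' closed IRanges used internally; `ranges_to_bed()` inverts it.
#'
#' @param pos integer vector of positions.
#' @rdname coordinates
#' @export
pos1_to_pos0 <- function(pos) as.integer(pos) - 1L

#' @rdname coordinates
#' @export
pos0_to_pos1 <- function(pos) as.integer(pos) + 1L

#' @param start0,end0 0-based half-open interval bounds.
#' @rdname coordinates
#' @export
bed_to_ranges <- function(start0, end0) {
  if (any(start0 >= end0)) stop("BED interval with start >= end")
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' @param ranges an IRanges object.
#' @rdname coordinates
#' @export
ranges_to_bed <- function(ranges) {
  data.frame(start = IRanges::start(ranges) - 1L, end = IRanges::end(ranges))
}

## ---- variant table construction ----------------------------------------

variant_table_cols <- c("chrom", "pos", "ref", "alt", "qual", "filter",
                        "var_class", "sv_type", "sv_len",
                        "gt_A", "gt_B", "gq_A", "gq_B", "dp_A", "dp_B", "ann")

new_variant_table <- function(df, samples) {
  for (col in setdiff(variant_table_cols, names(df)))
    df[[col]] <- rep(NA, nrow(df))
  df <- df[, variant_table_cols]
  df$pos <- as.integer(df$pos)
  df$qual <- as.numeric(df$qual)
  df$sv_len <- as.numeric(df$sv_len)
  df$gq_A <- as.numeric(df$gq_A); df$gq_B <- as.numeric(df$gq_B)
  df$dp_A <- as.numeric(df$dp_A); df$dp_B <- as.numeric(df$dp_B)
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  class(df) <- c("variant_table", "data.frame")
  df
}

info_field <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
         function(x) if (length(x)) sub(paste0("^;?", key, "="), "", x[1])
                     else NA_character_, character(1))
}

# Shared core of the two VCF readers.
read_vcf_table <- function(path, samples) {
  if (is.null(names(samples))) names(samples) <- c("A", "B")
  stopifnot(length(samples) == 2L, all(c("A", "B") %in% names(samples)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  vcf_samples <- colnames(v@gt)[-1]
  missing_samp <- setdiff(unname(samples), vcf_samples)
  if (length(missing_samp))
    stop("sample(s) not present in ", path, ": ",
         paste(missing_samp, collapse = ", "))
  if (n == 0L) {
    out <- new_variant_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), qual = numeric(), filter = character(),
                 ann = character(), stringsAsFactors = FALSE), samples)
    attr(out, "skipped") <- 0L
    return(out)
  }
  gt <- vcfR::extract.gt(v, "GT", convertNA = FALSE)
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  pick <- function(mat, s) if (is.null(mat)) rep(NA, n) else unname(mat[, s])
  info <- fix[, "INFO"]
  df <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = fix[, "FILTER"],
    sv_type = info_field(info, "SVTYPE"),
    sv_len = suppressWarnings(as.numeric(info_field(info, "SVLEN"))),
    gt_A = pick(gt, samples[["A"]]), gt_B = pick(gt, samples[["B"]]),
    gq_A = pick(gq, samples[["A"]]), gq_B = pick(gq, samples[["B"]]),
    dp_A = pick(dp, samples[["A"]]), dp_B = pick(dp, samples[["B"]]),
    ann = info_field(info, "ANN"),
    stringsAsFactors = FALSE)
  bad <- !gt_is_valid(df$gt_A) | !gt_is_valid(df$gt_B)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed GT skipped")
    df <- df[!bad, , drop = FALSE]
  }
  out <- new_variant_table(df, samples)
  attr(out, "skipped") <- sum(bad)
  out
}

classify_var_class <- function(ref, alt, gt_a, gt_b, sv_type) {
  n <- length(ref)
  out <- character(n)
  alts <- strsplit(alt, ",", fixed = TRUE)
  for (i in seq_len(n)) {
    if (!is.na(sv_type[i])) { out[i] <- "SV"; next }
    idx <- called_alt_indices(gt_a[i], gt_b[i])
    called <- if (length(idx)) alts[[i]][idx] else alts[[i]]
    called <- called[!is.na(called)]
    symbolic <- any(grepl("[<\\[\\]]", called))
    if (!symbolic && nchar(ref[i]) == 1L && length(called) &&
        all(nchar(called) == 1L)) out[i] <- "SNP"
    else out[i] <- "INDEL"
  }
  out
}

#' Read a joint two-sample small-variant VCF
#'
#' Reads a DeepVariant/GLNexus-style joint VCF into a variant table keyed by
#' the configured strain labels A and B, so downstream code never depends on
#' sample column order. Multi-allelic records are kept unsplit. Records are
#' classed SNP or INDEL from the called alleles; symbolic alleles are classed
#' SV only when the record carries SVTYPE.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples character vector of the two sample names as they appear in
#'   the VCF, named `c(A = ..., B = ...)` (unnamed vectors are taken in A, B
#'   order). A name absent from the file is a fatal error.
#' @return a `variant_table` data.frame; records with malformed GT strings
#'   are skipped with a warning and counted in `attr(x, "skipped")`.
#' @export
read_joint_vcf <- function(path, samples) {
  out <- read_vcf_table(path, samples)
  if (nrow(out)) {
    out$var_class <- classify_var_class(out$ref, out$alt, out$gt_A, out$gt_B,
                                        out$sv_type)
  }
  out
}

#' Read a structural-variant VCF (pbsv dialect)
#'
#' All yielded records are classed SV; FILTER is preserved verbatim. `sv_len`
#' comes from the SVLEN INFO field when present, otherwise from the
#' ref/alt length difference. Records lacking SVTYPE are skipped and counted.
#'
#' @inheritParams read_joint_vcf
#' @return a `variant_table` with `var_class == "SV"` throughout.
#' @export
read_sv_vcf <- function(path, samples) {
  out <- read_vcf_table(path, samples)
  no_type <- is.na(out$sv_type)
  if (any(no_type)) {
    warning(sum(no_type), " SV record(s) lacking SVTYPE skipped")
    att <- attributes(out)
    out <- out[!no_type, , drop = FALSE]
    attr(out, "samples") <- att$samples
    class(out) <- c("variant_table", "data.frame")
  }
  attr(out, "skipped_no_svtype") <- sum(no_type)
  if (nrow(out)) {
    out$var_class <- "SV"
    fallback <- is.na(out$sv_len)
    if (any(fallback)) {
      alt1 <- vapply(strsplit(out$alt[fallback], ","), `[`, character(1), 1L)
      symbolic <- grepl("[<\\[\\]]", alt1)
      len <- nchar(alt1) - nchar(out$ref[fallback])
      len[symbolic] <- NA_real_
      out$sv_len[fallback] <- len
    }
  }
  out
}

## ---- VCF writing --------------------------------------------------------

#' Write a variant table as VCF 4.2
#'
#' Emits a two-sample VCF that the package's readers parse back to an
#' identical table (field-level round trip on chrom/pos/alleles/qual/filter/
#' GT/GQ/ANN/SVTYPE/SVLEN).
#'
#' @param x a `variant_table`.
#' @param path output file path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(x, path, contigs = NULL) {
  samples <- attr(x, "samples")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=substrainr")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(samples[c("A", "B")])), collapse = "\t"))
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  info <- rep("", nrow(x))
  add <- function(info, key, val) {
    piece <- ifelse(is.na(val), "", paste0(key, "=", val))
    sep <- ifelse(nzchar(info) & nzchar(piece), ";", "")
    paste0(info, sep, piece)
  }
  info <- add(info, "SVTYPE", x$sv_type)
  info <- add(info, "SVLEN", ifelse(is.na(x$sv_len), NA,
                                    format(x$sv_len, scientific = FALSE,
                                           trim = TRUE)))
  info <- add(info, "ANN", x$ann)
  info[!nzchar(info)] <- "."
  fmt_call <- function(gt, gq, dp)
    paste(dot(gt), dot(gq), dot(dp), sep = ":")
  body <- if (nrow(x) == 0L) character() else
    paste(x$chrom, x$pos, ".", x$ref, x$alt, dot(x$qual), dot(x$filter),
          info, "GT:GQ:DP",
          fmt_call(x$gt_A, x$gq_A, x$dp_A),
          fmt_call(x$gt_B, x$gq_B, x$dp_B), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- reference and masks -------------------------------------------------

#' Read a soft-masked reference FASTA
#'
#' Case is preserved (the sequences are stored as BStringSet), so lowercase
#' soft-masked repeat runs remain recoverable.
#'
#' @param path FASTA file.
#' @return a [Biostrings::BStringSet] named by contig.
#' @export
read_masked_reference <- function(path) {
  ref <- Biostrings::readBStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Soft-mask intervals of a reference
#'
#' Extracts, per contig, the runs of lowercase bases as 1-based closed
#' IRanges. A structure built from the equivalent BED answers [is_masked()]
#' identically.
#'
#' @param ref BStringSet from [read_masked_reference()].
#' @return named list of IRanges (one element per contig).
#' @export
softmask_ranges <- function(ref) {
  out <- lapply(seq_along(ref), function(i) {
    s <- as.character(ref[[i]])
    hits <- gregexpr("[a-z]+", s)[[1]]
    if (hits[1] == -1L) return(IRanges::IRanges())
    IRanges::IRanges(start = as.integer(hits),
                     width = attr(hits, "match.length"))
  })
  names(out) <- names(ref)
  out
}

#' Load mask intervals from a BED3 file
#'
#' BED is 0-based half-open; intervals are converted to the internal 1-based
#' closed representation. A line with start >= end is a fatal parse error.
#'
#' @param path BED file (chrom, start, end; tab- or space-separated).
#' @return named list of IRanges.
#' @export
mask_from_bed <- function(path) {
  if (file.size(path) == 0L) return(list())
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (any(bed$start >= bed$end)) stop("BED interval with start >= end")
  split_idx <- split(seq_len(nrow(bed)), bed$chrom)
  lapply(split_idx, function(i)
    IRanges::reduce(bed_to_ranges(bed$start[i], bed$end[i])))
}

#' Query a mask at 1-based positions
#'
#' @param mask named list of IRanges ([softmask_ranges()] or
#'   [mask_from_bed()]).
#' @param chrom,pos parallel vectors of contig names and 1-based positions.
#' @return logical vector: TRUE where the position falls in a masked
#'   interval. Contigs absent from the mask are unmasked.
#' @export
is_masked <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ir <- mask[[ch]]
    if (is.null(ir) || length(ir) == 0L) next
    out[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos[sel], width = 1L), ir)
  }
  out
}

#' Write mask intervals to BED3
#'
#' @param mask named list of IRanges.
#' @param path output BED path (0-based half-open).
#' @export
write_mask_bed <- function(mask, path) {
  rows <- lapply(names(mask), function(ch) {
    ir <- mask[[ch]]
    if (length(ir) == 0L) return(NULL)
    b <- ranges_to_bed(ir)
    data.frame(chrom = ch, start = b$start, end = b$end)
  })
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- depth tracks --------------------------------------------------------

#' Read a BED-graph style depth track
#'
#' Expects four tab-separated columns (chrom, start, end, depth) with 0-based
#' half-open intervals, the bedGraph convention; that convention is kept in
#' the returned table.
#'
#' @param path TSV file.
#' @return data.frame with columns chrom, start, end, depth.
#' @export
read_depth_track <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "depth"))
  d$start <- as.numeric(d$start); d$end <- as.numeric(d$end)
  d$depth <- as.numeric(d$depth)
  validate_depth_track(d)
  d
}

#' Validate the tiling invariant of a depth track
#'
#' Within each contig, intervals must be sorted, non-overlapping, contiguous
#' from 0 and have non-negative depth; when contig lengths are supplied, the
#' track must end exactly at the contig length.
#'
#' @param track depth-track data.frame.
#' @param chrom_lengths optional named vector of contig lengths.
#' @return the track, invisibly; errors on violation.
#' @export
validate_depth_track <- function(track, chrom_lengths = NULL) {
  if (nrow(track) == 0L) stop("empty depth track")
  if (any(track$depth < 0)) stop("negative depth in track")
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    if (t$start[1] != 0) stop("track for ", ch, " does not start at 0")
    if (any(t$start >= t$end)) stop("empty/inverted interval in ", ch)
    if (nrow(t) > 1L && any(t$start[-1] != t$end[-nrow(t)]))
      stop("track for ", ch, " has gaps or overlaps")
    if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths) &&
        t$end[nrow(t)] != chrom_lengths[[ch]])
      stop("track for ", ch, " does not tile the full contig")
  }
  invisible(track)
}

#' Write a depth track as bedGraph-style TSV
#'
#' @param track depth-track data.frame (chrom, start, end, depth).
#' @param path output path.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a reference FASTA preserving case
#'
#' @param seqs named character vector or BStringSet of sequences.
#' @param path output path.
#' @param width line width.
#' @export
write_reference_fasta <- function(seqs, path, width = 70L) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
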
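# End-to-end orchestration: coverage -> filter/classify -> impact triage ->
# marker selection, with reproducible CSV/VCF/JSON outputs and a manifest.

#' Pipeline run configuration
#'
#' Bundles input paths, sample names and stage parameters for
#' [run_pipeline()]. All referenced files must exist at construction time.
#'
#' @param samples character vector `c(A = ..., B = ...)` of the two VCF
#'   sample names (strain A first); the names must be distinct.
#' @param small_vcf joint small-variant VCF path.
#' @param sv_vcf structural-variant VCF path (optional, NULL to skip SVs).
#' @param reference soft-masked reference FASTA path (optional; enables
#'   mask-based marker exclusion and genome-relative percentages).
#' @param depth_tracks named list (by strain label, "A"/"B") of depth-track
#'   paths (optional; enables the coverage stage).
#' @param excluded_bed BED of known assembly-error regions (optional).
#' @param classification a [classification_config()]; its `excluded_regions`
#'   slot is filled from `excluded_bed`.
#' @param marker_gq_min,marker_window,marker_anchor marker-selection
#'   parameters (GQ floor, window size in bp, 1-based window anchor).
#' @param select_markers set FALSE to skip the marker stage.
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(samples, small_vcf, sv_vcf = NULL, reference = NULL,
                       depth_tracks = NULL, excluded_bed = NULL,
                       classification = classification_config(),
                       marker_gq_min = 30, marker_window = 3e6,
                       marker_anchor = 1L, select_markers = TRUE,
                       outdir) {
  if (is.null(names(samples))) names(samples) <- c("A", "B")
  if (samples[["A"]] == samples[["B"]]) stop("sample names must be distinct")
  for (p in c(small_vcf, sv_vcf, reference, excluded_bed,
              unlist(depth_tracks)))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(samples = samples, small_vcf = small_vcf, sv_vcf = sv_vcf,
                 reference = reference, depth_tracks = depth_tracks,
                 excluded_bed = excluded_bed, classification = classification,
                 marker_gq_min = marker_gq_min, marker_window = marker_window,
                 marker_anchor = marker_anchor,
                 select_markers = isTRUE(select_markers), outdir = outdir),
            class = "run_config")
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full substrain-comparison pipeline
#'
#' Executes the stages in order (coverage summaries; quality filtering and
#' shared/unique classification; functional-impact triage; marker-panel
#' selection) and writes all outputs plus a JSON manifest with file
#' checksums, the configuration echo and the package version. Re-running
#' with identical inputs reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (list with `files`, `md5`, `counts`,
#'   `config`, `version`).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  files <- character(0)
  counts <- list()

  ## coverage
  if (!is.null(cfg$depth_tracks)) {
    tracks <- lapply(cfg$depth_tracks, read_depth_track)
    cov <- coverage_table(tracks)
    num <- vapply(cov, is.numeric, logical(1))
    cov[num] <- lapply(cov[num], function(x) round(x, 2))
    files <- c(files, write_csv_out(cov, out("coverage.csv")))
  }

  ## read + classify
  ccfg <- cfg$classification
  if (!is.null(cfg$excluded_bed))
    ccfg$excluded_regions <- mask_from_bed(cfg$excluded_bed)
  small <- read_joint_vcf(cfg$small_vcf, cfg$samples)
  counts$small_in <- nrow(small)
  variants <- small
  if (!is.null(cfg$sv_vcf)) {
    sv <- read_sv_vcf(cfg$sv_vcf, cfg$samples)
    counts$sv_in <- nrow(sv)
    variants <- rbind(small, sv)
    attr(variants, "samples") <- cfg$samples
    class(variants) <- c("variant_table", "data.frame")
  }
  classified <- classify_variants(variants, ccfg)
  counts$classified <- as.list(table(classified$category))

  ref <- NULL
  genome_length <- NULL
  if (!is.null(cfg$reference)) {
    ref <- read_masked_reference(cfg$reference)
    genome_length <- sum(Biostrings::width(ref))
  }

  for (cat in c("shared", "unique_A", "unique_B")) {
    sub <- classified[classified$category == cat, , drop = FALSE]
    sub <- sub[, variant_table_cols]
    attr(sub, "samples") <- cfg$samples
    class(sub) <- c("variant_table", "data.frame")
    files <- c(files, write_variant_vcf(sub, out(paste0(cat, ".vcf"))))
  }
  chrom_summary <- summarize_by_chrom(classified)
  num <- vapply(chrom_summary, is.numeric, logical(1)) &
    names(chrom_summary) != "n"
  chrom_summary[num] <- lapply(chrom_summary[num], function(x) round(x, 1))
  files <- c(files,
             write_csv_out(chrom_summary[chrom_summary$category == "shared", ],
                           out("shared_by_chrom.csv")),
             write_csv_out(chrom_summary[chrom_summary$category != "shared", ],
                           out("unique_by_chrom.csv")))
  tot <- variant_totals(classified, genome_length = genome_length)
  jsonlite::write_json(tot, out("totals.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, out("totals.json"))

  ## impact triage
  tri <- triage_impacts(classified)
  files <- c(files,
             write_csv_out(tri$reports, out("impact_variants.csv")),
             write_csv_out(tri$cell_counts, out("impact_cell_counts.csv")),
             write_csv_out(tri$effect_counts, out("effect_counts.csv")),
             write_csv_out(tri$annotation_counts,
                           out("annotation_counts.csv")))

  ## markers
  if (cfg$select_markers) {
    mask <- if (!is.null(ref)) softmask_ranges(ref) else NULL
    cand <- candidate_markers(classified, mask = mask,
                              gq_min = cfg$marker_gq_min,
                              window_size = cfg$marker_window,
                              anchor = cfg$marker_anchor)
    panel <- select_panel(cand)
    counts$marker_candidates <- nrow(cand)
    counts$markers <- nrow(panel)
    files <- c(files, write_csv_out(as.data.frame(panel),
                                    out("marker_panel.csv")))
    if (!is.null(ref)) {
      rep <- panel_report(panel, stats::setNames(Biostrings::width(ref),
                                                 names(ref)))
      files <- c(files, write_csv_out(rep$per_chrom,
                                      out("marker_report.csv")))
    }
  }

  manifest <- list(
    files = c(basename(files), "manifest.json"),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                  basename(files))),
    counts = counts,
    config = cfg[setdiff(names(cfg), "classification")],
    classification = unclass(cfg$classification[
      setdiff(names(cfg$classification), "excluded_regions")]),
    version = as.character(utils::packageVersion("substrainr")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
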
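# Functional-impact triage of SnpEff ANN annotations: pick out HIGH- and
# MODERATE-impact variants per sharing category and tabulate effects.

#' Most severe ANN impact of each variant
#'
#' Severity order is HIGH > MODERATE > LOW > MODIFIER. Variants with no ANN
#' annotation default to MODIFIER (no predicted functional consequence).
#'
#' @param ann character vector of raw ANN strings (NA or "" for none).
#' @return character vector of impact levels.
#' @export
max_impact <- function(ann) {
  vapply(ann, function(a) {
    entries <- parse_ann(if (is.na(a)) NA_character_ else a)
    if (nrow(entries) == 0L) return("MODIFIER")
    IMPACT_LEVELS[min(match(entries$impact, IMPACT_LEVELS))]
  }, character(1), USE.NAMES = FALSE)
}

# For one variant: the ANN entries at its most severe impact, in ANN order.
entries_at_max <- function(ann) {
  entries <- parse_ann(ann)
  if (nrow(entries) == 0L)
    return(data.frame(effect = character(), impact = character(),
                      gene = character(), stringsAsFactors = FALSE))
  lvl <- IMPACT_LEVELS[min(match(entries$impact, IMPACT_LEVELS))]
  entries[entries$impact == lvl, , drop = FALSE]
}

#' Impact triage of classified variants
#'
#' Selects the variants whose most severe ANN impact is HIGH or MODERATE for
#' each sharing category (shared, unique to either strain) and builds:
#' \itemize{
#'   \item `reports`: one row per (variant, gene annotated at the variant's
#'     top impact), with location, representative effect and variant class;
#'   \item `cell_counts`: per (category, impact) the number of distinct
#'     variants and of distinct genes (both tallies, since a variant may hit
#'     several genes);
#'   \item `effect_counts`: among non-discarded strain-unique variants, each
#'     variant counted once under its single most severe effect (ties broken
#'     by ANN order), across all impact levels;
#'   \item `annotation_counts`: the per-annotation tally of the same
#'     variants, for transparency.
#' }
#'
#' @param classified output of [classify_variants()].
#' @return list with elements `reports`, `cell_counts`, `effect_counts`,
#'   `annotation_counts`.
#' @export
triage_impacts <- function(classified) {
  keep <- classified[classified$category %in%
                       c("shared", "unique_A", "unique_B"), , drop = FALSE]
  top <- if (nrow(keep)) max_impact(keep$ann) else character()

  report_rows <- list()
  cell_rows <- list()
  for (cat in c("shared", "unique_A", "unique_B")) {
    for (imp in c("HIGH", "MODERATE")) {
      idx <- which(keep$category == cat & top == imp)
      if (length(idx)) {
        per_var <- lapply(idx, function(i) {
          e <- entries_at_max(keep$ann[i])
          genes <- unique(e$gene)
          data.frame(category = cat, impact = imp,
                     chrom = keep$chrom[i], pos = keep$pos[i],
                     gene = genes,
                     effect = vapply(genes, function(g)
                       e$effect[e$gene == g][1], character(1)),
                     var_class = keep$var_class[i],
                     stringsAsFactors = FALSE)
        })
        rep_df <- do.call(rbind, per_var)
        rownames(rep_df) <- NULL
        report_rows[[paste(cat, imp)]] <- rep_df
        n_genes <- length(unique(rep_df$gene))
      } else n_genes <- 0L
      cell_rows[[paste(cat, imp)]] <- data.frame(
        category = cat, impact = imp, n_variants = length(idx),
        n_genes = n_genes, stringsAsFactors = FALSE)
    }
  }
  reports <- if (length(report_rows)) do.call(rbind, report_rows) else
    data.frame(category = character(), impact = character(),
               chrom = character(), pos = integer(), gene = character(),
               effect = character(), var_class = character(),
               stringsAsFactors = FALSE)
  rownames(reports) <- NULL
  reports <- reports[order(reports$category, reports$impact, reports$chrom,
                           reports$pos, reports$gene), , drop = FALSE]
  rownames(reports) <- NULL
  cell_counts <- do.call(rbind, cell_rows)
  rownames(cell_counts) <- NULL

  uniq <- keep[keep$category %in% c("unique_A", "unique_B"), , drop = FALSE]
  one_effect <- vapply(uniq$ann, function(a) {
    e <- entries_at_max(a)
    if (nrow(e) == 0L) "unannotated" else e$effect[1]
  }, character(1), USE.NAMES = FALSE)
  effect_counts <- as.data.frame(table(effect = one_effect),
                                 stringsAsFactors = FALSE)
  names(effect_counts)[2] <- "n"
  effect_counts <- effect_counts[order(-effect_counts$n,
                                       effect_counts$effect), , drop = FALSE]
  rownames(effect_counts) <- NULL

  all_effects <- unlist(lapply(uniq$ann, function(a) parse_ann(
    if (is.na(a)) NA_character_ else a)$effect))
  annotation_counts <- as.data.frame(table(effect = all_effects),
                                     stringsAsFactors = FALSE)
  if (nrow(annotation_counts)) {
    names(annotation_counts)[2] <- "n"
    annotation_counts <- annotation_counts[order(-annotation_counts$n,
                                                 annotation_counts$effect), ,
                                           drop = FALSE]
  } else annotation_counts <- data.frame(effect = character(), n = integer())
  rownames(annotation_counts) <- NULL

  list(reports = reports, cell_counts = cell_counts,
       effect_counts = effect_counts, annotation_counts = annotation_counts)
}
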
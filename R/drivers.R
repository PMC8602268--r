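#' Consequence rules for non-synonymous classification
#'
#' Defines which annotation strings count as non-synonymous. Defaults follow
#' common somatic-annotation practice: out-of-frame and disruptive in-frame
#' frameshifts, nonsense (stop-gain), missense and splice variants; a
#' variant is also non-synonymous when its ClinVar class is VUS, likely
#' pathogenic or pathogenic, or when it carries a hotspot flag.
#'
#' @param nonsyn_categories Consequence strings treated as non-synonymous.
#' @param clinvar_categories ClinVar classes treated as non-synonymous.
#' @param include_hotspots Honour a logical `hotspot` column when present.
#' @return A `consequence_rules` list.
#' @export
consequence_rules <- function(
    nonsyn_categories = c("frameshift_variant",
                          "disruptive_inframe_deletion",
                          "disruptive_inframe_insertion",
                          "stop_gained", "stop_lost", "start_lost",
                          "missense_variant",
                          "splice_acceptor_variant", "splice_donor_variant",
                          "splice_region_variant"),
    clinvar_categories = c("VUS", "likely_pathogenic", "pathogenic"),
    include_hotspots = TRUE) {
  if (length(nonsyn_categories) == 0) {
    abort("nonsyn_categories must be non-empty")
  }
  structure(list(nonsyn_categories = nonsyn_categories,
                 clinvar_categories = clinvar_categories,
                 include_hotspots = include_hotspots),
            class = "consequence_rules")
}

#' Classify records as non-synonymous or other
#'
#' Adds an `effect` column (`"non_synonymous"` / `"other"`) based on the
#' `consequence` column, an optional `clinvar` column, and an optional
#' logical `hotspot` column. Records with no annotation at all are classed
#' `"other"` and counted in a message.
#'
#' @param records Record tibble with a `consequence` column (optionally
#'   `clinvar`, `hotspot`).
#' @param rules A [consequence_rules()] object.
#' @return `records` with an `effect` column appended.
#' @export
classify_consequence <- function(records, rules = consequence_rules()) {
  stopifnot(inherits(rules, "consequence_rules"))
  csq <- records[["consequence"]] %||% rep(NA_character_, nrow(records))
  clinvar <- records[["clinvar"]] %||% rep(NA_character_, nrow(records))
  hotspot <- records[["hotspot"]] %||% rep(FALSE, nrow(records))
  unannotated <- is.na(csq) & is.na(clinvar) & !hotspot
  if (any(unannotated)) {
    inform(paste0(sum(unannotated),
                  " record(s) without annotation classified as 'other'"))
  }
  nonsyn <- (!is.na(csq) & csq %in% rules$nonsyn_categories) |
    (!is.na(clinvar) & clinvar %in% rules$clinvar_categories) |
    (rules$include_hotspots & hotspot %in% TRUE)
  records$effect <- ifelse(nonsyn, "non_synonymous", "other")
  records
}

# severity ranking for driver-cell rendering; higher = more severe
DRIVER_SEVERITY <- c(none = 0L, `promoter/UTR` = 1L, missense = 2L,
                     `frameshift/nonsense` = 3L)

TRUNCATING_CSQ <- c("frameshift_variant", "disruptive_inframe_deletion",
                    "disruptive_inframe_insertion", "stop_gained",
                    "stop_lost", "start_lost",
                    "splice_acceptor_variant", "splice_donor_variant")

#' Tally driver-gene mutations per sample
#'
#' Intersects mutation records with driver-gene intervals (1-based
#' inclusive, via [IRanges::findOverlaps()]) and reports, for every
#' sample x gene, the most severe overlapping category, ranked
#' `frameshift/nonsense > missense > promoter/UTR > none`. Coding-interval
#' overlaps are categorised from the record's consequence (truncating
#' consequences map to `frameshift/nonsense`, missense to `missense`; other
#' or unannotated coding overlaps do not register); any overlap with an
#' interval whose `region_label` is not `coding` registers as
#' `promoter/UTR`.
#'
#' @param records Record tibble with `clone_id` (or `sample`), `chrom`,
#'   `pos`, `ref`, `consequence`.
#' @param genes Driver tibble from [read_driver_genes()].
#' @param rules A [consequence_rules()] (reserved for ClinVar/hotspot
#'   escalation of coding overlaps).
#' @return Tibble, one row per sample x gene, with a `category` column.
#' @export
tally_driver_mutations <- function(records, genes,
                                   rules = consequence_rules()) {
  sample_col <- if ("clone_id" %in% names(records)) "clone_id" else "sample"
  if (!sample_col %in% names(records)) {
    abort("records need a clone_id or sample column")
  }
  samples <- sort(unique(records[[sample_col]]))
  grid <- tidyr::expand_grid(sample = samples, gene = unique(genes$gene))
  if (nrow(records) == 0) {
    grid$category <- "none"
    return(grid)
  }
  # variant footprint: pos .. pos + nchar(ref) - 1 (1-based inclusive)
  ref_len <- ifelse(is.na(records$ref) | !grepl("^[ACGTN]+$", records$ref),
                    1L, nchar(records$ref))
  vr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$pos, records$pos + ref_len - 1)
  )
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(vr, gr)
  if (length(hits) == 0) {
    grid$category <- "none"
    return(grid)
  }
  eff <- classify_consequence(records, rules)
  h <- tibble(
    sample = records[[sample_col]][S4Vectors::queryHits(hits)],
    gene = genes$gene[S4Vectors::subjectHits(hits)],
    region = genes$region_label[S4Vectors::subjectHits(hits)],
    consequence = records$consequence[S4Vectors::queryHits(hits)],
    effect = eff$effect[S4Vectors::queryHits(hits)]
  ) |>
    mutate(category = dplyr::case_when(
      .data$region != "coding" ~ "promoter/UTR",
      .data$consequence %in% TRUNCATING_CSQ ~ "frameshift/nonsense",
      .data$consequence %in% "missense_variant" ~ "missense",
      .data$effect == "non_synonymous" ~ "missense",
      TRUE ~ "none"
    ))
  best <- h |>
    mutate(rank = DRIVER_SEVERITY[.data$category]) |>
    group_by(.data$sample, .data$gene) |>
    summarise(category = names(DRIVER_SEVERITY)[max(.data$rank) + 1L],
              .groups = "drop")
  grid |>
    left_join(best, by = c("sample", "gene")) |>
    mutate(category = dplyr::coalesce(.data$category, "none"))
}
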
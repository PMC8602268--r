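toy_genes <- function() {
  tibble::tibble(
    gene = c("TERT", "TERT", "TP53"),
    chrom = c("chr5", "chr5", "chr17"),
    start = c(1000, 500, 7000),
    end = c(2000, 999, 7500),
    region_label = c("coding", "promoter", "coding")
  )
}

rec_row <- function(chrom, pos, consequence = NA, clinvar = NA,
                    hotspot = FALSE, clone = "s1", ref = "A") {
  tibble::tibble(clone_id = clone, chrom = chrom, pos = pos, ref = ref,
                 alt = "T", var_class = "SBS", consequence = consequence,
                 clinvar = clinvar, hotspot = hotspot)
}

test_that("consequence classification honours categories, ClinVar and hotspots", {
  rec <- dplyr::bind_rows(
    rec_row("chr5", 1500, "missense_variant"),
    rec_row("chr5", 1500, "synonymous_variant"),
    rec_row("chr5", 1500, "intron_variant", clinvar = "pathogenic"),
    rec_row("chr5", 1500, "synonymous_variant", hotspot = TRUE),
    rec_row("chr5", 1500, NA)
  )
  out <- suppressMessages(classify_consequence(rec))
  expect_equal(out$effect, c("non_synonymous", "other", "non_synonymous",
                             "non_synonymous", "other"))
  expect_message(classify_consequence(rec_row("chr5", 1, NA)),
                 "without annotation")
  no_hot <- consequence_rules(include_hotspots = FALSE)
  out2 <- classify_consequence(rec_row("chr5", 1, "synonymous_variant",
                                       hotspot = TRUE), no_hot)
  expect_equal(out2$effect, "other")
  expect_error(consequence_rules(nonsyn_categories = character()),
               "non-empty")
})

test_that("driver tallies take the most severe overlapping category", {
  rec <- dplyr::bind_rows(
    rec_row("chr5", 1500, "missense_variant"),              # TERT coding
    rec_row("chr5", 750, "upstream_gene_variant"),          # TERT promoter
    rec_row("chr17", 7200, "stop_gained", clone = "s2"),    # TP53 truncating
    rec_row("chr17", 6999, "missense_variant", clone = "s2") # 1 bp outside
  )
  tal <- suppressMessages(tally_driver_mutations(rec, toy_genes()))
  expect_equal(nrow(tal), 4)  # 2 samples x 2 genes
  get <- function(s, g) tal$category[tal$sample == s & tal$gene == g]
  expect_equal(get("s1", "TERT"), "missense")
  expect_equal(get("s2", "TP53"), "frameshift/nonsense")
  expect_equal(get("s2", "TERT"), "none")
  expect_equal(get("s1", "TP53"), "none")
})

test_that("interval boundaries are 1-based inclusive", {
  genes <- tibble::tibble(gene = "G", chrom = "chr1", start = 100, end = 200,
                          region_label = "coding")
  inside <- dplyr::bind_rows(rec_row("chr1", 100, "missense_variant"),
                             rec_row("chr1", 200, "missense_variant"))
  outside <- dplyr::bind_rows(rec_row("chr1", 99, "missense_variant"),
                              rec_row("chr1", 201, "missense_variant"))
  tal_in <- tally_driver_mutations(inside, genes)
  tal_out <- tally_driver_mutations(outside, genes)
  expect_equal(tal_in$category, "missense")
  expect_equal(tal_out$category, "none")
  # a deletion whose ref footprint reaches the interval start overlaps
  del <- rec_row("chr1", 98, "frameshift_variant", ref = "AAA")
  expect_equal(tally_driver_mutations(del, genes)$category,
               "frameshift/nonsense")
})

test_that("severity never decreases when records are added", {
  genes <- toy_genes()
  sev <- c(none = 0, `promoter/UTR` = 1, missense = 2,
           `frameshift/nonsense` = 3)
  base <- rec_row("chr5", 750, "upstream_gene_variant")
  more <- dplyr::bind_rows(base, rec_row("chr5", 1500, "missense_variant"))
  most <- dplyr::bind_rows(more, rec_row("chr5", 1500, "stop_gained"))
  cats <- vapply(list(base, more, most), function(r) {
    t <- tally_driver_mutations(r, genes)
    t$category[t$gene == "TERT"]
  }, character(1))
  expect_true(all(diff(sev[cats]) >= 0))
  expect_equal(unname(cats), c("promoter/UTR", "missense",
                               "frameshift/nonsense"))
})

test_that("overlap assignment agrees with a brute-force scan on 1000 random variants", {
  set.seed(77)
  genes <- tibble::tibble(
    gene = paste0("G", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample(1:50000, 20),
    region_label = "coding"
  )
  genes$end <- genes$start + sample(100:3000, 20)
  rec <- tibble::tibble(
    clone_id = sample(paste0("s", 1:4), 1000, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample(1:55000, 1000, replace = TRUE),
    ref = "A", alt = "T", var_class = "SBS",
    consequence = "missense_variant"
  )
  tal <- tally_driver_mutations(rec, genes)
  # brute force: any record of the sample inside any interval of the gene
  for (i in seq_len(nrow(tal))) {
    s <- tal$sample[i]; g <- tal$gene[i]
    gi <- genes[genes$gene == g, ]
    ri <- rec[rec$clone_id == s, ]
    hit <- FALSE
    for (j in seq_len(nrow(gi))) {
      hit <- hit || any(ri$chrom == gi$chrom[j] & ri$pos >= gi$start[j] &
                          ri$pos <= gi$end[j])
    }
    expect_equal(tal$category[i] != "none", hit)
  }
})
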
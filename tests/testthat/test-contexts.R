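test_that("catalogs have the canonical sizes and unique labels", {
  expect_length(sbs96_catalog(), 96)
  expect_length(dbs78_catalog(), 78)
  expect_length(id83_catalog(), 83)
  expect_length(sv16_catalog(), 16)
  for (vc in c("SBS", "DBS", "INDEL", "SV")) {
    expect_false(anyDuplicated(context_catalog(vc)) > 0)
  }
})

test_that("SBS classification collapses to the pyrimidine strand", {
  expect_equal(classify_sbs("C", "T", "ACG"), "A[C>T]G")
  expect_equal(classify_sbs("G", "A", "CGT"), "A[C>T]G")
  expect_equal(classify_sbs("T", "G", "TTT"), "T[T>G]T")
  expect_error(classify_sbs("C", "T", "AAG"), "mismatch")
  expect_warning(out <- classify_sbs("C", "T", "NCG"), "N in flank")
  expect_true(is.na(out))
})

test_that("SBS classification is strand symmetric over all 192 inputs and covers all 96 categories", {
  bases <- c("A", "C", "G", "T")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  labels <- character(0)
  for (f5 in bases) for (ref in bases) for (f3 in bases) {
    for (alt in setdiff(bases, ref)) {
      fl <- paste0(f5, ref, f3)
      lab <- classify_sbs(ref, alt, fl)
      rc_fl <- paste0(comp(f3), comp(ref), comp(f5))
      lab_rc <- classify_sbs(comp(ref), comp(alt), rc_fl)
      expect_identical(lab_rc, lab)
      labels <- c(labels, lab)
    }
  }
  expect_setequal(labels, sbs96_catalog())
  expect_true(all(labels %in% sbs96_catalog()))
})

test_that("DBS classification is strand symmetric and covers all 78 categories", {
  bases <- c("A", "C", "G", "T")
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste0(substr(x, 2, 2), substr(x, 1, 1)))
  labels <- character(0)
  for (r1 in bases) for (r2 in bases) {
    ref <- paste0(r1, r2)
    for (a1 in setdiff(bases, r1)) for (a2 in setdiff(bases, r2)) {
      alt <- paste0(a1, a2)
      lab <- classify_dbs(ref, alt)
      expect_identical(classify_dbs(rc(ref), rc(alt)), lab)
      labels <- c(labels, lab)
    }
  }
  expect_setequal(labels, dbs78_catalog())
})

test_that("DBS spot checks match the canonical catalog conventions", {
  expect_equal(classify_dbs("CC", "TT"), "CC>TT")
  expect_equal(classify_dbs("GG", "AA"), "CC>TT")
  expect_equal(classify_dbs("AT", "CG"), "AT>CG")
  expect_error(classify_dbs("AC", "AC"), "must change")
  expect_error(classify_dbs("AC", "AG"), "must change")
})

test_that("indel spot cases follow the repeat/microhomology schema", {
  g <- Biostrings::DNAStringSet(
    c(chr1 = "GGAACTTTTTGCAGCAGCAGCATTTACGGACCTATTTAGCCGGTAGCTAGGGTCAA")
  )
  # one T deleted from the TTTTT homopolymer at 6-10
  expect_equal(
    classify_indel(tibble::tibble(chrom = "chr1", pos = 5, ref = "CT",
                                  alt = "C"), g),
    "1:Del:T:5")
  # GG inserted with no adjacent copies
  expect_equal(
    classify_indel(tibble::tibble(chrom = "chr1", pos = 3, ref = "A",
                                  alt = "AGG"), g),
    "2:Ins:R:0")
  # one CAG copy deleted from a (CAG)x3 tandem repeat
  expect_equal(
    classify_indel(tibble::tibble(chrom = "chr1", pos = 11, ref = "GCAG",
                                  alt = "G"), g),
    "3:Del:R:3")
  # 4-bp deletion of TAGC whose downstream flank TACCC shares a 2-bp prefix
  # (TA) and no full tandem copy exists -> microhomology class
  g2 <- Biostrings::DNAStringSet(
    c(chr1 = "AAAAAAAAAATAGCTACCCAAAAAAAAAA")
  )
  del <- tibble::tibble(chrom = "chr1", pos = 10, ref = "ATAGC", alt = "A")
  expect_equal(classify_indel(del, g2), "4:Del:M:2")
  # complex block substitution is excluded with a warning
  expect_warning(
    out <- classify_indel(tibble::tibble(chrom = "chr1", pos = 5, ref = "CTT",
                                         alt = "CAGG"), g),
    "complex")
  expect_true(is.na(out))
})

test_that("indel classifier agrees with the brute-force scanner on 1000 random indels", {
  genome <- generate_toy_genome(5e4, seed = 919)
  s <- as.character(genome[[1]])
  idx <- random_indels(s, 1000, seed = 920, chrom = names(genome))
  got <- classify_indel(idx, genome)
  expected <- vapply(seq_len(nrow(idx)), function(i) {
    oracle_id83(idx$type[i], idx$seq[i], s, idx$a[i])
  }, character(1))
  expect_identical(got, expected)
  expect_true(all(got %in% id83_catalog()))
})

test_that("SV length bins partition the positive lengths", {
  expect_equal(classify_sv("DEL", 25000), "DEL_10kb-100kb")
  expect_equal(classify_sv("TRA", NA), "TRA")
  expect_equal(classify_sv("INV", 10000), "INV_1kb-10kb")
  expect_equal(classify_sv("INV", 10001), "INV_10kb-100kb")
  expect_equal(classify_sv("DUP", 2e7), "DUP_>10Mb")
  expect_warning(lab <- classify_sv("DEL", 500), "folded")
  expect_equal(lab, "DEL_1kb-10kb")
  # every length maps to exactly one bin
  lens <- c(2, 999, 1000, 1001, 9999, 1e4, 1e4 + 1, 99999, 1e5, 1e5 + 1,
            1e6, 1e6 + 1, 1e7, 1e7 + 1, 5e8)
  labs <- suppressWarnings(classify_sv(rep("DEL", length(lens)), lens))
  expect_true(all(labs %in% sv16_catalog()))
  expect_true(all(!is.na(labs)))
  expect_warning(out <- classify_sv("DEL", NA), "missing length")
  expect_true(is.na(out))
  expect_error(classify_sv("FOO", 5000), "unknown SV type")
})

test_that("spectrum matrices conserve counts and keep empty clones", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAACGAAACGAAACG"))
  rec <- tibble::tibble(
    clone_id = c("c1", "c1", "c1"),
    chrom = "chr1", pos = c(4, 9, 14), ref = "C", alt = "T",
    var_class = "SBS", sv_type = NA_character_, sv_len = NA_real_,
    filter = "PASS", consequence = NA_character_
  )
  mat <- build_spectrum_matrix(rec, "SBS", g, clones = c("c1", "c2"))
  expect_equal(dim(mat), c(96, 2))
  expect_equal(sum(mat), 3)
  expect_equal(mat["A[C>T]G", "c1"], 3)
  expect_equal(sum(mat[, "c2"]), 0)
  expect_equal(colSums(mat), c(c1 = 3, c2 = 0))
})

test_that("spectrum TSVs round-trip", {
  m <- matrix(0L, 16, 2, dimnames = list(sv16_catalog(), c("a", "b")))
  m["TRA", "a"] <- 3L
  path <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(m, path)
  expect_equal(read_spectrum_tsv(path), m)
})
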
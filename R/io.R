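#' Read somatic variants from a VCF file
#'
#' Parses a VCF 4.x file into a tibble of mutation records, classifying each
#' alternate allele as a single base substitution (SBS), doublet substitution
#' (DBS), small insertion/deletion (INDEL) or structural variant (SV).
#' Multi-allelic rows are split into one record per alternate allele.
#' Structural variants are recognised from symbolic alternate alleles
#' (`<DEL>`, `<DUP>`, ...) with `SVTYPE`/`END` INFO keys, or from breakend
#' notation; breakend mates on another chromosome become translocations
#' (`TRA`), same-chromosome breakends get their span `|mate_pos - pos|` as
#' length and a type inferred from bracket orientation.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param pass_only If `TRUE` (default), keep only records whose FILTER field
#'   is `PASS` (downstream burden and spectrum analyses conventionally use
#'   PASS calls only).
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `var_class`, `sv_type`, `sv_len`, `filter`, `consequence` (taken from an
#'   `ANN_SIMPLE` or `CSQ_CLASS` INFO key when present, else `NA`).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'              "chr1\t100\t.\tA\tT\t.\tPASS\t."), vcf)
#' read_vcf_variants(vcf)
#' @export
read_vcf_variants <- function(path, pass_only = TRUE) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_mutation_records())
  }
  fix <- as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  pos_num <- suppressWarnings(as.numeric(fix$POS))
  if (anyNA(pos_num)) {
    bad <- which(is.na(pos_num))[1]
    abort(paste0("VCF format error at data line ", bad,
                 ": non-numeric POS '", fix$POS[bad], "'"))
  }

  rec <- tibble(
    chrom = fix$CHROM,
    pos = pos_num,
    ref = toupper(fix$REF),
    alt = fix$ALT,
    filter = fix$FILTER %||% ".",
    info = fix$INFO %||% "."
  )
  # split multi-allelic rows: one record per alt
  rec <- tidyr::separate_rows(rec, "alt", sep = ",")
  rec$alt <- ifelse(grepl("^<|\\[|\\]", rec$alt), rec$alt, toupper(rec$alt))

  rec <- classify_var_class(rec)
  n_skip <- sum(is.na(rec$var_class))
  if (n_skip > 0) {
    warn(paste0(n_skip, " record(s) skipped: unclassifiable allele or ",
                "unknown SVTYPE"))
    rec <- filter(rec, !is.na(.data$var_class))
  }
  rec$consequence <- extract_info_key(rec$info, "ANN_SIMPLE") %|na|%
    extract_info_key(rec$info, "CSQ_CLASS")
  rec <- select(rec, -"info")
  if (isTRUE(pass_only)) rec <- filter(rec, .data$filter == "PASS")
  rec
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

empty_mutation_records <- function() {
  tibble(chrom = character(), pos = numeric(), ref = character(),
         alt = character(), var_class = character(), sv_type = character(),
         sv_len = numeric(), filter = character(), consequence = character())
}

extract_info_key <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info,
                                perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
  out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", info[hit],
                  perl = TRUE)
  out
}

# assign var_class / sv_type / sv_len to a raw record tibble (has $info)
classify_var_class <- function(rec) {
  svtype <- extract_info_key(rec$info, "SVTYPE")
  endpos <- suppressWarnings(as.numeric(extract_info_key(rec$info, "END")))
  symbolic <- grepl("^<.+>$", rec$alt)
  breakend <- grepl("\\[|\\]", rec$alt)
  is_sv <- symbolic | breakend | !is.na(svtype)

  var_class <- rep(NA_character_, nrow(rec))
  sv_type <- rep(NA_character_, nrow(rec))
  sv_len <- rep(NA_real_, nrow(rec))

  # small variants
  small <- !is_sv & grepl("^[ACGTN]+$", rec$ref) & grepl("^[ACGTN]+$", rec$alt)
  lr <- nchar(rec$ref)
  la <- nchar(rec$alt)
  var_class[small & lr == 1 & la == 1] <- "SBS"
  var_class[small & lr == 2 & la == 2] <- "DBS"
  var_class[small & lr != la] <- "INDEL"
  # equal-length blocks >2 bp (MNVs) stay NA -> skipped with a warning

  for (i in which(is_sv)) {
    ty <- svtype[i]
    if (is.na(ty) && symbolic[i]) ty <- gsub("[<>]", "", rec$alt[i])
    if (!is.na(ty) && ty %in% c("BND", "TRA") && breakend[i]) {
      mate <- parse_breakend(rec$alt[i])
      if (is.null(mate)) next
      if (mate$chrom != rec$chrom[i]) {
        var_class[i] <- "SV"; sv_type[i] <- "TRA"
      } else {
        var_class[i] <- "SV"
        sv_type[i] <- mate$orient_type
        sv_len[i] <- abs(mate$pos - rec$pos[i])
      }
    } else if (!is.na(ty) && ty %in% c("DEL", "DUP", "INV")) {
      var_class[i] <- "SV"; sv_type[i] <- ty
      if (!is.na(endpos[i])) sv_len[i] <- endpos[i] - rec$pos[i]
    } else if (!is.na(ty) && ty == "TRA") {
      var_class[i] <- "SV"; sv_type[i] <- "TRA"
    }
    # other SVTYPEs (INS etc.) remain NA -> skipped with a warning
  }
  rec$var_class <- var_class
  rec$sv_type <- sv_type
  rec$sv_len <- sv_len
  rec
}

# parse a VCF breakend ALT ("t[chr:pos[", "]chr:pos]t", ...) into its mate
# coordinates and a junction-orientation SV type (DEL-like +-, DUP-like -+,
# INV-like ++/--)
parse_breakend <- function(alt) {
  m <- regmatches(alt, regexec("([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  bracket <- m[2]
  seq_first <- !grepl("^[\\[\\]]", alt)
  orient_type <- if (bracket == "[" && seq_first) "DEL"       # t[p[  (+-)
    else if (bracket == "]" && !seq_first) "DUP"              # ]p]t  (-+)
    else "INV"                                                # t]p] / [p[t
  list(chrom = m[3], pos = as.numeric(m[4]), orient_type = orient_type)
}

#' Fetch flanking sequence around a position from an indexed FASTA
#'
#' Returns the uppercase reference sequence of length `2k + 1` centred on
#' `pos` (1-based). Vectorised over `chrom`/`pos`.
#'
#' @param genome Path to a FASTA file (a `.fai` index is created if missing)
#'   or a [Biostrings::DNAStringSet].
#' @param chrom Sequence name(s).
#' @param pos 1-based centre position(s).
#' @param k Flank width in bp on each side (`k = 0` returns the centre base).
#' @return Character vector of sequences, each of length `2k + 1`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' fetch_flanks(g, "chr1", 4, 1)  # "GTA"
#' @export
fetch_flanks <- function(genome, chrom, pos, k = 1) {
  stopifnot(k >= 0, length(chrom) == length(pos))
  seqs <- load_genome(genome)
  if (!all(chrom %in% names(seqs))) {
    missing_chr <- setdiff(unique(chrom), names(seqs))
    abort(paste0("sequence(s) not in genome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  oob <- pos - k < 1 | pos + k > lens[chrom]
  if (any(oob)) {
    abort(
      paste0("flank window out of bounds at ", chrom[oob][1], ":",
             pos[oob][1], " (k=", k, ")"),
      class = "mutaccum_boundary_error"
    )
  }
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- Biostrings::extractAt(
      seqs[[ch]],
      IRanges::IRanges(start = pos[idx] - k, end = pos[idx] + k)
    )
    out[idx] <- toupper(as.character(v))
  }
  if (any(grepl("[^ACGTN]", out))) {
    abort("genome contains bases other than ACGTN in requested window")
  }
  out
}

# accept a FASTA path or an in-memory DNAStringSet
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    fa <- Rsamtools::FaFile(genome)
    if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
    return(Rsamtools::scanFa(fa))
  }
  abort("genome must be a FASTA path or a DNAStringSet")
}

#' Write mutation records to a VCF file
#'
#' Inverse of [read_vcf_variants()] for small variants and symbolic SVs;
#' used by the synthetic-data generator and for round-trip testing.
#'
#' @param records Tibble of mutation records (see [read_vcf_variants()]).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_variants <- function(records, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
    '##INFO=<ID=ANN_SIMPLE,Number=1,Type=String,Description="Consequence">',
    '##FILTER=<ID=PASS,Description="All filters passed">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  info <- rep(".", nrow(records))
  sv <- !is.na(records$var_class) & records$var_class == "SV"
  info[sv] <- ifelse(
    records$sv_type[sv] == "TRA",
    "SVTYPE=TRA",
    sprintf("SVTYPE=%s;END=%d", records$sv_type[sv],
            as.integer(records$pos[sv] + records$sv_len[sv]))
  )
  has_csq <- !is.na(records[["consequence"]] %||% rep(NA, nrow(records)))
  if (any(has_csq)) {
    info[has_csq] <- ifelse(
      info[has_csq] == ".",
      paste0("ANN_SIMPLE=", records$consequence[has_csq]),
      paste0(info[has_csq], ";ANN_SIMPLE=", records$consequence[has_csq])
    )
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  records$chrom, as.integer(records$pos), records$ref,
                  records$alt, records[["filter"]] %||% "PASS", info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a signature definition matrix (COSMIC layout)
#'
#' @param path TSV with context labels in the first column and one column per
#'   signature; each signature column must be nonnegative and sum to 1
#'   (tolerance 1e-6).
#' @return A `signature_model` object (see [signature_model()]).
#' @export
read_signature_definitions <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  defs <- as.matrix(tbl[, -1])
  rownames(defs) <- tbl[[1]]
  signature_model(defs)
}

#' Construct a signature model
#'
#' Bundles a context-by-signature definition matrix with (optionally) a
#' per-sample exposure table.
#'
#' @param definitions Nonnegative numeric matrix, contexts x signatures,
#'   each column summing to 1 within 1e-6. Row and column names required.
#' @param exposures Optional tibble of per-sample exposures as returned by
#'   [read_exposure_table()].
#' @return An object of class `signature_model` with elements `contexts`,
#'   `signatures`, `definitions`, `exposures`.
#' @export
signature_model <- function(definitions, exposures = NULL) {
  stopifnot(is.matrix(definitions), !is.null(rownames(definitions)),
            !is.null(colnames(definitions)))
  if (any(definitions < 0)) {
    abort("signature definitions must be nonnegative")
  }
  colsum <- colSums(definitions)
  if (any(abs(colsum - 1) > 1e-6)) {
    bad <- colnames(definitions)[abs(colsum - 1) > 1e-6][1]
    abort(paste0("signature column '", bad, "' does not sum to 1 (got ",
                 format(colsum[bad]), ")"))
  }
  structure(
    list(contexts = rownames(definitions),
         signatures = colnames(definitions),
         definitions = definitions,
         exposures = exposures),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", length(x$signatures), " signatures over ",
      length(x$contexts), " contexts\n", sep = "")
  if (!is.null(x$exposures)) {
    cat("  exposures: ", nrow(x$exposures), " samples\n", sep = "")
  }
  invisible(x)
}

#' Read a per-sample signature exposure table
#'
#' Expects the layout of the PCAWG "signatures in samples" tables: one row
#' per sample with a sample identifier column, a cancer-type column and one
#' nonnegative column per signature.
#'
#' @param path TSV path.
#' @param sample_col,type_col Names of the sample and cancer-type columns.
#' @return Tibble with columns `sample`, `cancer_type` and one column per
#'   signature. A header-only file yields a zero-row tibble.
#' @export
read_exposure_table <- function(path, sample_col = "Sample Names",
                                type_col = "Cancer Types") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(tbl)
  find_col <- function(want, fallback_pattern) {
    if (want %in% nm) return(want)
    hit <- grep(fallback_pattern, nm, ignore.case = TRUE, value = TRUE)
    if (length(hit) >= 1) return(hit[1])
    NA_character_
  }
  sc <- find_col(sample_col, "sample")
  tc <- find_col(type_col, "cancer|type")
  if (is.na(tc)) {
    abort("exposure table format error: no cancer-type column found")
  }
  if (is.na(sc)) {
    abort("exposure table format error: no sample column found")
  }
  sig_cols <- setdiff(nm, c(sc, tc))
  if (nrow(tbl) > 0) {
    vals <- as.matrix(tbl[, sig_cols])
    if (!is.numeric(vals)) abort("exposure table has non-numeric exposures")
    if (any(vals < 0)) {
      abort("exposure table validation error: negative exposure values")
    }
  }
  out <- tbl
  names(out)[names(out) == sc] <- "sample"
  names(out)[names(out) == tc] <- "cancer_type"
  select(out, "sample", "cancer_type", dplyr::all_of(sig_cols))
}

#' Read clone metadata
#'
#' @param path TSV with columns `clone_id`, `patient_id`, `age`, `group`.
#' @return Validated tibble. Errors if clone ids repeat, ages are not
#'   positive, or a patient appears in more than one group.
#' @export
read_clone_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           clone_id = "c", patient_id = "c",
                           age = "d", group = "c"))
  validate_clone_metadata(tbl)
}

validate_clone_metadata <- function(tbl) {
  need <- c("clone_id", "patient_id", "age", "group")
  if (!all(need %in% names(tbl))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tbl$clone_id)) abort("clone_id values must be unique")
  if (any(tbl$age <= 0)) abort("ages must be positive (years)")
  split_groups <- tbl |>
    distinct(.data$patient_id, .data$group) |>
    count(.data$patient_id) |>
    filter(n > 1)
  if (nrow(split_groups) > 0) {
    abort(paste0("patient(s) assigned to more than one group: ",
                 paste(split_groups$patient_id, collapse = ", ")))
  }
  as_tibble(tbl)
}

#' Read a driver-gene interval table
#'
#' @param path TSV with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `region_label` (defaults to `"coding"`); one row per
#'   interval, 1-based inclusive coordinates.
#' @return Validated tibble.
#' @export
read_driver_genes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    abort(paste0("driver table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!"region_label" %in% names(tbl)) tbl$region_label <- "coding"
  if (nrow(tbl) == 0) abort("driver table has no intervals")
  if (any(tbl$start > tbl$end)) abort("driver intervals must have start <= end")
  as_tibble(tbl)
}
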
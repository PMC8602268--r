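#' Classify single base substitutions into SBS96 contexts
#'
#' Maps each substitution to one of the 96 trinucleotide categories
#' `X[R>A]Y` on the pyrimidine reference strand: variants whose reference
#' base is a purine are reverse-complemented (flanks and alleles) before
#' labelling.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param flanks Trinucleotide strings centred on the variant (as returned by
#'   [fetch_flanks()] with `k = 1`); the centre base must equal `ref`.
#' @return Character vector of SBS96 labels; `NA` (with a warning) where the
#'   flank contains an `N`.
#' @examples
#' classify_sbs("C", "T", "ACG")  # "A[C>T]G"
#' classify_sbs("G", "A", "CGT")  # same context, purine strand
#' @export
classify_sbs <- function(ref, alt, flanks) {
  stopifnot(length(ref) == length(alt), length(ref) == length(flanks))
  if (length(ref) == 0) return(character(0))
  if (any(nchar(flanks) != 3)) abort("flanks must be trinucleotides (k = 1)")
  has_n <- grepl("N", flanks) | ref == "N" | alt == "N"
  ok <- !has_n
  if (any(substr(flanks[ok], 2, 2) != ref[ok])) {
    i <- which(ok)[substr(flanks[ok], 2, 2) != ref[ok]][1]
    abort(paste0("flank centre '", substr(flanks[i], 2, 2),
                 "' does not match ref '", ref[i],
                 "': genome/VCF mismatch"))
  }
  out <- rep(NA_character_, length(ref))
  if (any(has_n)) {
    warn(paste0(sum(has_n), " SBS record(s) skipped: N in flanking sequence"))
  }
  purine <- ok & ref %in% c("A", "G")
  ref2 <- ref; alt2 <- alt; fl2 <- flanks
  ref2[purine] <- chartr("AG", "TC", ref[purine])
  alt2[purine] <- chartr("ACGT", "TGCA", alt[purine])
  fl2[purine] <- revcomp(flanks[purine])
  out[ok] <- paste0(substr(fl2[ok], 1, 1), "[", ref2[ok], ">", alt2[ok], "]",
                    substr(fl2[ok], 3, 3))
  out[!ok] <- NA_character_
  out
}

#' Classify doublet substitutions into DBS78 contexts
#'
#' Maps each 2-bp substitution to one of the 78 canonical doublet categories.
#' Doublets whose reference is not one of the ten canonical reference
#' doublets are reverse-complemented on both reference and alternate; for
#' palindromic reference doublets the alternate is flipped when needed to
#' match the fixed canonical alternate list.
#'
#' @param ref,alt 2-bp reference/alternate allele strings; both bases must
#'   differ between `ref` and `alt`.
#' @return Character vector of DBS78 labels.
#' @examples
#' classify_dbs("GG", "AA")  # "CC>TT"
#' @export
classify_dbs <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (length(ref) == 0) return(character(0))
  if (any(nchar(ref) != 2 | nchar(alt) != 2)) {
    abort("DBS records must have 2-bp ref and alt")
  }
  same_first <- substr(ref, 1, 1) == substr(alt, 1, 1)
  same_second <- substr(ref, 2, 2) == substr(alt, 2, 2)
  if (any(same_first | same_second)) {
    abort("invalid DBS: both bases must change between ref and alt")
  }
  catalog <- dbs78_catalog()
  fwd <- paste0(ref, ">", alt)
  rev <- paste0(revcomp(ref), ">", revcomp(alt))
  out <- ifelse(fwd %in% catalog, fwd, rev)
  if (any(!out %in% catalog)) {
    abort(paste0("doublet not representable in DBS78: ",
                 fwd[!out %in% catalog][1]))
  }
  out
}

#' Classify indels into ID83 contexts
#'
#' Implements the COSMIC 83-category indel schema: 1-bp deletions and
#' insertions split by base (C/T after strand collapsing) and homopolymer
#' length; longer indels split by length and tandem-repeat count; deletions
#' not in a tandem repeat scanned for flanking microhomology. Indels must be
#' left-aligned (as emitted by standard somatic callers); the classifier
#' trusts the input alignment.
#'
#' @param records Tibble with columns `chrom`, `pos`, `ref`, `alt` holding
#'   VCF-style indels (anchor-base convention).
#' @param genome FASTA path or `DNAStringSet`.
#' @param window Repeat/homology scan window each side, bp. The category caps
#'   (5+/6+) make anything beyond the default irrelevant.
#' @return Character vector of ID83 labels; `NA` (warned) for complex
#'   substitutions that are neither pure insertions nor pure deletions.
#' @export
classify_indel <- function(records, genome, window = 100) {
  if (nrow(records) == 0) return(character(0))
  seqs <- load_genome(genome)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  out <- rep(NA_character_, nrow(records))
  n_complex <- 0L
  for (i in seq_len(nrow(records))) {
    ev <- indel_event(records$ref[i], records$alt[i])
    if (is.null(ev)) { n_complex <- n_complex + 1L; next }
    chrom <- records$chrom[i]
    pos <- records$pos[i]
    # 1-based coordinates of the affected segment
    if (ev$type == "Del") {
      seg_start <- pos + ev$offset
      seg_end <- seg_start + nchar(ev$seq) - 1
    } else {
      # insertion lands between pos+offset-1 and pos+offset: empty segment,
      # so upstream ends at pos+offset-1 and downstream starts at pos+offset
      seg_start <- pos + ev$offset
      seg_end <- seg_start - 1
    }
    up_start <- max(1, seg_start - window)
    down_end <- min(lens[[chrom]], seg_end + window)
    upstream <- substr_genome(seqs, chrom, up_start, seg_start - 1)
    downstream <- substr_genome(seqs, chrom, seg_end + 1, down_end)
    out[i] <- classify_indel_core(ev$type, ev$seq, upstream, downstream)
  }
  if (n_complex > 0) {
    warn(paste0(n_complex, " complex indel(s) (block substitutions) excluded",
                " from ID83 classification"))
  }
  out
}

substr_genome <- function(seqs, chrom, start, end) {
  if (end < start) return("")
  toupper(as.character(Biostrings::subseq(seqs[[chrom]], start, end)))
}

# reduce a VCF ref/alt pair to a pure insertion or deletion event;
# offset = number of leading shared anchor bases
indel_event <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) return(NULL)
  np <- 0L
  while (np < min(lr, la) &&
         substr(ref, np + 1, np + 1) == substr(alt, np + 1, np + 1)) {
    np <- np + 1L
  }
  if (lr > la && np == la) {
    list(type = "Del", seq = substr(ref, np + 1, lr), offset = np)
  } else if (la > lr && np == lr) {
    list(type = "Ins", seq = substr(alt, np + 1, la), offset = np)
  } else {
    NULL  # complex: both alleles retain unshared sequence
  }
}

# count whole copies of 'unit' reading forward from the start of 'seq'
count_copies_forward <- function(unit, seq) {
  l <- nchar(unit); n <- 0L
  while (substr(seq, n * l + 1, (n + 1) * l) == unit) n <- n + 1L
  n
}

# count whole copies of 'unit' reading backward from the end of 'seq'
count_copies_backward <- function(unit, seq) {
  l <- nchar(unit); L <- nchar(seq); n <- 0L
  while ((n + 1) * l <= L &&
         substr(seq, L - (n + 1) * l + 1, L - n * l) == unit) n <- n + 1L
  n
}

# longest proper prefix of 'unit' matching the start of 'seq'
prefix_match <- function(unit, seq) {
  lmax <- min(nchar(unit) - 1L, nchar(seq))
  m <- 0L
  while (m < lmax &&
         substr(unit, m + 1, m + 1) == substr(seq, m + 1, m + 1)) m <- m + 1L
  m
}

# longest proper suffix of 'unit' matching the end of 'seq'
suffix_match <- function(unit, seq) {
  lu <- nchar(unit); ls <- nchar(seq)
  lmax <- min(lu - 1L, ls)
  m <- 0L
  while (m < lmax &&
         substr(unit, lu - m, lu - m) == substr(seq, ls - m, ls - m)) m <- m + 1L
  m
}

# pure-string ID83 classification given the event and its flanking sequence
classify_indel_core <- function(type, seq, upstream, downstream) {
  L <- nchar(seq)
  if (L == 1) {
    base <- if (seq %in% c("A", "G")) chartr("AG", "TC", seq) else seq
    run <- count_copies_forward(seq, downstream) +
      count_copies_backward(seq, upstream)
    if (type == "Del") {
      n <- min(run + 1L, 6L)          # run includes the deleted base
      paste0("1:Del:", base, ":", n)
    } else {
      n <- min(run, 5L)
      paste0("1:Ins:", base, ":", n)
    }
  } else {
    lbin <- min(L, 5L)
    copies <- count_copies_forward(seq, downstream) +
      count_copies_backward(seq, upstream)
    if (type == "Ins") {
      paste0(lbin, ":Ins:R:", min(copies, 5L))
    } else if (copies >= 1) {
      paste0(lbin, ":Del:R:", min(copies + 1L, 6L))
    } else {
      mh <- max(prefix_match(seq, downstream), suffix_match(seq, upstream))
      if (mh >= 1) {
        paste0(lbin, ":Del:M:", min(mh, 5L))
      } else {
        paste0(lbin, ":Del:R:1")
      }
    }
  }
}

#' Classify structural variants into the 16-category type x length schema
#'
#' Deletions, duplications and inversions are binned by length into
#' 1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb and >10 Mb (left-open,
#' right-closed intervals in bp); translocations form a single category with
#' no length. Lengths of 1 kb or less are folded into the first bin with a
#' warning, since the schema starts at 1 kb.
#'
#' @param sv_type Character vector: `DEL`, `DUP`, `INV` or `TRA`.
#' @param sv_len Lengths in bp (`NA` allowed, and required, for `TRA`).
#' @return Character vector of SV context labels; `NA` (warned) where a
#'   non-translocation lacks a length.
#' @examples
#' classify_sv("DEL", 25000)  # "DEL_10kb-100kb"
#' classify_sv("TRA", NA)     # "TRA"
#' @export
classify_sv <- function(sv_type, sv_len) {
  stopifnot(length(sv_type) == length(sv_len))
  if (length(sv_type) == 0) return(character(0))
  bad_type <- !sv_type %in% c("DEL", "DUP", "INV", "TRA")
  if (any(bad_type)) {
    abort(paste0("unknown SV type: ", sv_type[bad_type][1]))
  }
  out <- rep(NA_character_, length(sv_type))
  tra <- sv_type == "TRA"
  out[tra] <- "TRA"
  need_len <- !tra
  no_len <- need_len & (is.na(sv_len) | sv_len <= 0)
  if (any(no_len)) {
    warn(paste0(sum(no_len), " SV record(s) excluded: missing length for ",
                "non-translocation"))
  }
  sub1kb <- need_len & !no_len & sv_len <= 1000
  if (any(sub1kb)) {
    warn(paste0(sum(sub1kb), " SV record(s) of 1 kb or less folded into the ",
                "1kb-10kb bin"))
  }
  idx <- need_len & !no_len
  bin <- cut(pmax(sv_len[idx], 1001), c(1e3, 1e4, 1e5, 1e6, 1e7, Inf),
             labels = SV_LENGTH_BINS, right = TRUE)
  out[idx] <- paste0(sv_type[idx], "_", as.character(bin))
  out
}

#' Classify a table of mutation records into context categories
#'
#' Adds a `context` column to a record tibble, dispatching on `var_class`.
#' Records that cannot be classified (N in flank, complex indels, SVs without
#' length) get `NA` and are warned about by the per-class classifiers.
#'
#' @param records Tibble from [read_vcf_variants()] (any mix of classes);
#'   an optional `clone_id` column is carried through.
#' @param genome FASTA path or `DNAStringSet` (needed for SBS and INDEL).
#' @return `records` with a `context` column appended.
#' @export
classify_variants <- function(records, genome = NULL) {
  records$context <- NA_character_
  is_sbs <- records$var_class == "SBS"
  if (any(is_sbs)) {
    if (is.null(genome)) abort("SBS classification needs a reference genome")
    fl <- fetch_flanks(genome, records$chrom[is_sbs], records$pos[is_sbs], 1)
    records$context[is_sbs] <-
      classify_sbs(records$ref[is_sbs], records$alt[is_sbs], fl)
  }
  is_dbs <- records$var_class == "DBS"
  if (any(is_dbs)) {
    records$context[is_dbs] <-
      classify_dbs(records$ref[is_dbs], records$alt[is_dbs])
  }
  is_ind <- records$var_class == "INDEL"
  if (any(is_ind)) {
    if (is.null(genome)) abort("indel classification needs a reference genome")
    records$context[is_ind] <- classify_indel(records[is_ind, ], genome)
  }
  is_sv <- records$var_class == "SV"
  if (any(is_sv)) {
    records$context[is_sv] <-
      classify_sv(records$sv_type[is_sv], records$sv_len[is_sv])
  }
  records
}

#' Build a context spectrum matrix (catalog x clones)
#'
#' Aggregates classified records of one variant class into a count matrix
#' whose rows are the full catalog in canonical order and whose columns are
#' clones. Clones with zero variants of the class are retained as all-zero
#' columns. Column sums equal the number of classified (non-`NA`-context)
#' records per clone.
#'
#' @param records Tibble with `clone_id` and either a `context` column or the
#'   columns needed by [classify_variants()].
#' @param var_class Variant class of the spectrum.
#' @param genome Genome, forwarded to [classify_variants()] when contexts are
#'   not yet assigned.
#' @param clones Optional character vector fixing the column set/order.
#' @return Integer matrix, catalog x clones.
#' @export
build_spectrum_matrix <- function(records, var_class = "SBS", genome = NULL,
                                  clones = NULL) {
  if (!"clone_id" %in% names(records)) {
    abort("records need a clone_id column to build per-clone spectra")
  }
  catalog <- context_catalog(var_class)
  recs <- filter(records, .data$var_class == !!var_class)
  if (!"context" %in% names(recs) ||
      (nrow(recs) > 0 && all(is.na(recs$context)))) {
    recs <- classify_variants(recs, genome)
  }
  recs <- filter(recs, !is.na(.data$context))
  clones <- clones %||% sort(unique(records$clone_id))
  mat <- matrix(0L, nrow = length(catalog), ncol = length(clones),
                dimnames = list(catalog, clones))
  if (nrow(recs) > 0) {
    bad <- !recs$context %in% catalog
    if (any(bad)) {
      abort(paste0("context label outside ", var_class, " catalog: ",
                   recs$context[bad][1]))
    }
    tab <- recs |> count(.data$clone_id, .data$context)
    mat[cbind(match(tab$context, catalog), match(tab$clone_id, clones))] <-
      as.integer(tab$n)
  }
  mat
}

#' Convert a spectrum matrix to a tidy tibble
#'
#' @param mat Matrix from [build_spectrum_matrix()].
#' @param var_class Variant class label to attach.
#' @return Tibble with columns `clone_id`, `var_class`, `context`, `count`.
#' @export
spectrum_as_tibble <- function(mat, var_class = "SBS") {
  tibble(
    clone_id = rep(colnames(mat), each = nrow(mat)),
    var_class = var_class,
    context = rep(rownames(mat), times = ncol(mat)),
    count = as.integer(mat)
  )
}

#' Write / read a spectrum matrix as TSV
#'
#' Rows are catalog labels in canonical order, columns are clone ids.
#'
#' @param mat Spectrum matrix.
#' @param path Output path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_spectrum_tsv <- function(mat, path) {
  df <- data.frame(context = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  mat
}
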
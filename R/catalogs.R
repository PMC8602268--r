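#' Mutation-context catalogs
#'
#' Canonical, ordered category labels for the four variant classes handled by
#' the package: the 96 trinucleotide substitution contexts (pyrimidine
#' reference strand), the 78 canonical doublet substitutions, the 83 indel
#' categories (size, repeat context, microhomology), and a 16-category
#' structural-variant schema (type x length bin, with translocations as a
#' single unbinned category).
#'
#' Indel labels use 1-based deletion repeat counts: `1:Del:T:5` is a single T
#' deleted from a homopolymer of five T's (capped at `6` for 6+), whereas
#' insertion counts are the number of pre-existing copies of the inserted
#' sequence (`0`-`5`, capped at 5+). Microhomology categories `k:Del:M:m` are
#' deletions of length k (k = 5 meaning 5+) with m bases of flanking homology.
#'
#' @param var_class One of `"SBS"`, `"DBS"`, `"INDEL"`, `"SV"`.
#' @return Character vector of category labels in canonical order.
#' @examples
#' head(context_catalog("SBS"))
#' length(context_catalog("SV"))
#' @export
context_catalog <- function(var_class = c("SBS", "DBS", "INDEL", "SV")) {
  var_class <- match.arg(var_class)
  switch(var_class,
    SBS = sbs96_catalog(),
    DBS = dbs78_catalog(),
    INDEL = id83_catalog(),
    SV = sv16_catalog()
  )
}

BASES <- c("A", "C", "G", "T")

#' @rdname context_catalog
#' @export
sbs96_catalog <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (f5 in BASES) {
      for (f3 in BASES) {
        out <- c(out, paste0(f5, "[", s, "]", f3))
      }
    }
  }
  out
}

# the ten canonical reference doublets and their COSMIC-fixed alternate lists
DBS78_ALTS <- list(
  AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
  AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
  CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
  CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
  CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
  GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
  TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
  TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
  TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
  TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
)

#' @rdname context_catalog
#' @export
dbs78_catalog <- function() {
  unlist(purrr::imap(DBS78_ALTS, function(alts, ref) paste0(ref, ">", alts)),
         use.names = FALSE)
}

#' @rdname context_catalog
#' @export
id83_catalog <- function() {
  c(
    paste0("1:Del:C:", 1:6),
    paste0("1:Del:T:", 1:6),
    paste0("1:Ins:C:", 0:5),
    paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 1:6),
    paste0("3:Del:R:", 1:6),
    paste0("4:Del:R:", 1:6),
    paste0("5:Del:R:", 1:6),
    paste0("2:Ins:R:", 0:5),
    paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5),
    paste0("5:Ins:R:", 0:5),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

SV_LENGTH_BINS <- c("1kb-10kb", "10kb-100kb", "100kb-1Mb", "1Mb-10Mb", ">10Mb")

#' @rdname context_catalog
#' @export
sv16_catalog <- function() {
  c(as.vector(t(outer(c("DEL", "DUP", "INV"), SV_LENGTH_BINS, paste, sep = "_"))),
    "TRA")
}

# reverse complement for plain character vectors of ACGTN strings
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}
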
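# Independent brute-force oracles used to verify the classifiers and the
# NNLS solver. These deliberately re-derive every quantity by naive scanning
# on the full sequence string / dense search, sharing no code with R/.

# ID83 category by naive scanning of the whole genome string.
# type: "Del" (segment [a, b] removed) or "Ins" (seq inserted after pos a-1,
# i.e. before character a).
oracle_id83 <- function(type, seq, s, a, b = a + nchar(seq) - 1) {
  L <- nchar(seq)
  n <- nchar(s)
  if (type == "Del") {
    left_end <- a - 1
    right_start <- b + 1
  } else {
    left_end <- a - 1
    right_start <- a
  }
  if (L == 1) {
    base <- seq
    run <- if (type == "Del") 1L else 0L
    i <- right_start
    while (i <= n && substring(s, i, i) == base) { run <- run + 1L; i <- i + 1L }
    i <- left_end
    while (i >= 1 && substring(s, i, i) == base) { run <- run + 1L; i <- i - 1L }
    lab_base <- if (base %in% c("A", "G")) chartr("AG", "TC", base) else base
    if (type == "Del") {
      paste0("1:Del:", lab_base, ":", min(run, 6L))
    } else {
      paste0("1:Ins:", lab_base, ":", min(run, 5L))
    }
  } else {
    copies <- if (type == "Del") 1L else 0L
    i <- right_start
    while (i + L - 1 <= n && substring(s, i, i + L - 1) == seq) {
      copies <- copies + 1L; i <- i + L
    }
    i <- left_end
    while (i - L + 1 >= 1 && substring(s, i - L + 1, i) == seq) {
      copies <- copies + 1L; i <- i - L
    }
    lbin <- min(L, 5L)
    if (type == "Ins") return(paste0(lbin, ":Ins:R:", min(copies, 5L)))
    if (copies >= 2) return(paste0(lbin, ":Del:R:", min(copies, 6L)))
    # microhomology: partial prefix of seq after the deletion, or partial
    # suffix before it
    mh <- 0L
    m <- 0L
    while (m < L - 1 && right_start + m <= n &&
           substring(s, right_start + m, right_start + m) ==
           substring(seq, m + 1, m + 1)) m <- m + 1L
    mh <- max(mh, m)
    m <- 0L
    while (m < L - 1 && left_end - m >= 1 &&
           substring(s, left_end - m, left_end - m) ==
           substring(seq, L - m, L - m)) m <- m + 1L
    mh <- max(mh, m)
    if (mh >= 1) paste0(lbin, ":Del:M:", min(mh, 5L))
    else paste0(lbin, ":Del:R:1")
  }
}

# draw random indels on a genome string, returned in VCF anchor convention
random_indels <- function(s, n, seed, chrom = "chr1") {
  set.seed(seed)
  out <- vector("list", n)
  slen <- nchar(s)
  for (i in seq_len(n)) {
    type <- sample(c("Del", "Ins"), 1)
    L <- sample(1:6, 1)
    if (type == "Del") {
      a <- sample(seq(200, slen - 200), 1)
      seq_i <- substring(s, a, a + L - 1)
      ref <- substring(s, a - 1, a + L - 1)
      alt <- substring(s, a - 1, a - 1)
      pos <- a - 1
    } else {
      pos <- sample(seq(200, slen - 200), 1)
      seq_i <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
      ref <- substring(s, pos, pos)
      alt <- paste0(ref, seq_i)
      a <- pos + 1
    }
    out[[i]] <- tibble::tibble(chrom = chrom, pos = pos, ref = ref,
                               alt = alt, type = type, seq = seq_i, a = a)
  }
  dplyr::bind_rows(out)
}

# residual of a candidate nonnegative contribution vector
nnls_residual <- function(A, b, x) sqrt(sum((A %*% x - b)^2))

# write a minimal VCF from raw field strings
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               lines), path)
  path
}
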
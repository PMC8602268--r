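#' Configure a synthetic organoid cohort
#'
#' Defines the generating model for synthetic cohorts: clones nested in
#' patients, donor ages uniform on a range, per-patient accumulation slopes
#' (group slope plus a zero-truncated normal random effect), Poisson (or
#' exact) per-clone counts, and per-group signature mixtures for drawing
#' context spectra.
#'
#' Defaults mirror a liver-organoid study design: four donor groups
#' (healthy, alcoholic cirrhosis, NASH, PSC) with 7/5/5/3 patients, two
#' clones per patient, ages 20-70, and healthy-liver accumulation rates of
#' 46 SBS and 9 indels per year (DBS and SV rates are set low, matching the
#' scarcity of those classes in normal tissue). All groups share the same
#' generating rates by default, i.e. the null of no disease effect.
#'
#' @param n_patients Named integer vector: patients per group.
#' @param clones_per_patient Integer, or length-2 range sampled uniformly.
#' @param age_range Length-2 numeric, years.
#' @param slopes Named list: per-group named numeric of mutations/year per
#'   variant class. A single named numeric is recycled to all groups.
#' @param patient_sd Named numeric per variant class: SD of the per-patient
#'   slope random effect (mutations/year).
#' @param count_noise `"poisson"` or `"none"` (exact means).
#' @param signature_mix Named list: per-group mixing weights over the SBS
#'   signature columns (must sum to 1). `NULL` = uniform.
#' @param seed Integer RNG seed; a fixed seed makes every downstream output
#'   byte-identical.
#' @param genome_len Toy reference length, bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = c(healthy = 7, ALC = 5, NASH = 5, PSC = 3),
                       clones_per_patient = 2,
                       age_range = c(20, 70),
                       slopes = c(SBS = 46, INDEL = 9, DBS = 0.6, SV = 0.3),
                       patient_sd = c(SBS = 5, INDEL = 1, DBS = 0.1,
                                      SV = 0.05),
                       count_noise = c("poisson", "none"),
                       signature_mix = NULL,
                       seed = 1,
                       genome_len = 1e5) {
  count_noise <- match.arg(count_noise)
  n_patients <- unlist(n_patients)  # accept YAML-style named lists
  if (is.null(names(n_patients))) abort("n_patients must be named by group")
  if (!is.list(slopes)) {
    slopes <- purrr::map(setNames(names(n_patients), names(n_patients)),
                         function(g) slopes)
  }
  if (any(unlist(slopes) < 0)) abort("slopes must be nonnegative")
  if (any(patient_sd < 0)) abort("patient_sd must be nonnegative")
  if (length(clones_per_patient) == 1) {
    clones_per_patient <- rep(clones_per_patient, 2)
  }
  stopifnot(length(age_range) == 2, age_range[1] > 0,
            age_range[2] >= age_range[1])
  if (!is.null(signature_mix)) {
    for (g in names(signature_mix)) {
      w <- signature_mix[[g]]
      if (any(w < 0)) abort("signature mixing weights must be nonnegative")
      if (abs(sum(w) - 1) > 1e-6) {
        abort("signature mixing weights must sum to 1 (tolerance 1e-6)")
      }
    }
  }
  structure(
    list(n_patients = n_patients, clones_per_patient = clones_per_patient,
         age_range = age_range, slopes = slopes, patient_sd = patient_sd,
         count_noise = count_noise, signature_mix = signature_mix,
         seed = as.integer(seed), genome_len = genome_len),
    class = "sim_config"
  )
}

#' Simulate a cohort of clonal organoid genomes
#'
#' Draws patients, ages, per-patient slopes and per-clone mutation counts
#' from a [sim_config()]. Patient slopes are `group slope + N(0, patient_sd)`
#' truncated at zero; clone counts are `Poisson(slope_i * age)` (or the
#' exact mean when `count_noise = "none"`). Fully deterministic given the
#' config seed.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_cohort` list with `meta` (tibble: `clone_id`,
#'   `patient_id`, `age`, `group`), and `truth` (list of tibbles:
#'   `clone_counts`, `patient_slopes`, `group_params`).
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = c(healthy = 3), seed = 7))
#' co$meta
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  classes <- names(cfg$patient_sd)
  meta <- list(); slopes_out <- list(); counts_out <- list()
  for (g in names(cfg$n_patients)) {
    gslope <- cfg$slopes[[g]]
    for (p in seq_len(cfg$n_patients[[g]])) {
      pid <- paste0(g, p)
      age <- runif(1, cfg$age_range[1], cfg$age_range[2])
      psl <- pmax(0, gslope[classes] + rnorm(length(classes), 0,
                                             cfg$patient_sd[classes]))
      slopes_out[[pid]] <- tibble(patient_id = pid, group = g,
                                  var_class = classes,
                                  slope = unname(psl))
      n_clones <- if (cfg$clones_per_patient[1] == cfg$clones_per_patient[2]) {
        cfg$clones_per_patient[1]
      } else {
        sample(cfg$clones_per_patient[1]:cfg$clones_per_patient[2], 1)
      }
      for (cl in seq_len(n_clones)) {
        cid <- paste0(pid, "-", letters[cl])
        meta[[cid]] <- tibble(clone_id = cid, patient_id = pid, age = age,
                              group = g)
        mu <- psl * age
        cnt <- if (cfg$count_noise == "poisson") rpois(length(mu), mu) else mu
        counts_out[[cid]] <- tibble(clone_id = cid, var_class = classes,
                                    count = unname(cnt))
      }
    }
  }
  group_params <- purrr::imap(cfg$slopes, function(s, g) {
    tibble(group = g, var_class = names(s), slope = unname(s))
  }) |> bind_rows() |>
    filter(.data$group %in% names(cfg$n_patients))
  structure(
    list(meta = bind_rows(meta),
         truth = list(clone_counts = bind_rows(counts_out),
                      patient_slopes = bind_rows(slopes_out),
                      group_params = group_params),
         config = cfg),
    class = "sim_cohort"
  )
}

#' Draw a context spectrum from a signature mixture
#'
#' Samples `n` mutations from the categorical distribution
#' `definitions %*% mix` and tabulates them over the model's context catalog.
#'
#' @param n Number of mutations to draw.
#' @param mix Nonnegative mixing weights over the model's signatures,
#'   summing to 1 (tolerance 1e-6).
#' @param model A [signature_model()].
#' @param seed Optional seed for a self-contained draw.
#' @return Named integer vector over the model's contexts, summing to `n`.
#' @export
simulate_catalog <- function(n, mix, model, seed = NULL) {
  stopifnot(inherits(model, "signature_model"), n >= 0)
  if (length(mix) != length(model$signatures)) {
    abort("mix length must equal the number of model signatures")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6) {
    abort("mix must be nonnegative and sum to 1 (tolerance 1e-6)")
  }
  if (!is.null(seed)) set.seed(seed)
  probs <- as.vector(model$definitions %*% mix)
  counts <- if (n == 0) rep(0L, length(probs)) else {
    as.integer(stats::rmultinom(1, n, probs))
  }
  setNames(counts, model$contexts)
}

#' Build a synthetic, well-separated signature model
#'
#' Constructs `n_signatures` probability distributions over a context
#' catalog, each concentrated on its own disjoint block of contexts with a
#' small flat background — a deliberately idealised stand-in for real COSMIC
#' definitions, suited to exact- and statistical-recovery testing.
#'
#' @param n_signatures Number of signatures.
#' @param var_class Catalog to use (`"SBS"`, `"DBS"`, `"INDEL"`, `"SV"`).
#' @param peak_mass Total probability mass placed on each signature's own
#'   context block.
#' @param seed Seed for the within-block weights.
#' @return A [signature_model()] with signatures named `SYN1`, `SYN2`, ...
#' @export
synthetic_signature_model <- function(n_signatures = 4, var_class = "SBS",
                                      peak_mass = 0.85, seed = 1) {
  catalog <- context_catalog(var_class)
  k <- length(catalog)
  stopifnot(n_signatures >= 1, n_signatures <= k, peak_mass > 0,
            peak_mass < 1)
  set.seed(seed)
  block <- split(seq_len(k), rep(seq_len(n_signatures), length.out = k))
  defs <- matrix(0, nrow = k, ncol = n_signatures,
                 dimnames = list(catalog, paste0("SYN", seq_len(n_signatures))))
  for (j in seq_len(n_signatures)) {
    w <- stats::rgamma(length(block[[j]]), shape = 2)
    defs[block[[j]], j] <- peak_mass * w / sum(w)
    defs[, j] <- defs[, j] + (1 - peak_mass) / k
  }
  defs <- sweep(defs, 2, colSums(defs), "/")
  signature_model(defs)
}

#' Generate a toy reference genome
#'
#' A single-contig random genome that contains every trinucleotide by
#' construction (all 64 trinucleotides are concatenated at the start, so all
#' 32 pyrimidine-centred SBS contexts are placeable).
#'
#' @param genome_len Total length, bp (minimum 500).
#' @param seed RNG seed.
#' @param contig Contig name.
#' @return A `DNAStringSet` of length 1.
#' @export
generate_toy_genome <- function(genome_len = 1e5, seed = 1,
                                contig = "chr_syn") {
  stopifnot(genome_len >= 500)
  set.seed(seed)
  trinucs <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  prefix <- paste(trinucs, collapse = "")
  n_rand <- genome_len - nchar(prefix)
  seq <- paste0(prefix, paste(sample(BASES, n_rand, replace = TRUE),
                              collapse = ""))
  setNames(Biostrings::DNAStringSet(seq), contig)
}

#' Write a synthetic dataset to disk
#'
#' Materialises a simulated cohort as a file tree: a toy reference FASTA
#' (with `.fai`), one VCF per clone whose SBS records reproduce the clone's
#' drawn SBS96 spectrum exactly when re-classified against the toy genome,
#' a metadata TSV, true count tables for the non-SBS classes, and a
#' ground-truth JSON.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param model SBS [signature_model()] used to draw spectra (defaults to a
#'   4-signature synthetic model).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the output paths and the per-clone true
#'   SBS spectra (matrix catalog x clones).
#' @export
write_synthetic_dataset <- function(cohort, model = NULL, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  model <- model %||% synthetic_signature_model(4, "SBS", seed = 1)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", outdir))
  }
  if (file.access(outdir, 2) != 0) {
    abort(paste0("output directory not writable: ", outdir))
  }
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)

  set.seed(cfg$seed + 1L)
  catalog <- context_catalog("SBS")
  sbs_counts <- cohort$truth$clone_counts |>
    filter(.data$var_class == "SBS") |>
    left_join(select(cohort$meta, "clone_id", "group"), by = "clone_id")
  spectra <- matrix(0L, nrow = length(catalog), ncol = nrow(sbs_counts),
                    dimnames = list(catalog, sbs_counts$clone_id))
  for (i in seq_len(nrow(sbs_counts))) {
    g <- sbs_counts$group[i]
    mix <- cfg$signature_mix[[g]] %||%
      rep(1 / length(model$signatures), length(model$signatures))
    spectra[, i] <- simulate_catalog(round(sbs_counts$count[i]), mix, model)
  }

  genome <- generate_toy_genome(cfg$genome_len, seed = cfg$seed + 2L)
  placed <- try(place_sbs_records(spectra, genome), silent = TRUE)
  if (inherits(placed, "try-error")) {
    # retry once with a larger genome so every context has enough sites
    genome <- generate_toy_genome(cfg$genome_len * 4, seed = cfg$seed + 3L)
    placed <- place_sbs_records(spectra, genome)
  }

  fa_path <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(genome, fa_path)
  Rsamtools::indexFa(fa_path)
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  for (cid in colnames(spectra)) {
    rec <- placed[placed$clone_id == cid, , drop = FALSE]
    rec <- arrange(rec, .data$pos)
    write_vcf_variants(rec, file.path(outdir, "vcf", paste0(cid, ".vcf")),
                       contigs = contig_len)
  }
  readr::write_tsv(cohort$meta, file.path(outdir, "metadata.tsv"))
  for (vc in setdiff(unique(cohort$truth$clone_counts$var_class), "SBS")) {
    tab <- cohort$truth$clone_counts |> filter(.data$var_class == vc)
    readr::write_tsv(tab, file.path(outdir, paste0("counts_", vc, ".tsv")))
  }
  truth_json <- list(
    clone_counts = cohort$truth$clone_counts,
    patient_slopes = cohort$truth$patient_slopes,
    group_params = cohort$truth$group_params,
    sbs_spectra = as.data.frame(spectra),
    seed = cfg$seed
  )
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(list(outdir = outdir, genome = fa_path,
                 vcf_dir = file.path(outdir, "vcf"),
                 metadata = file.path(outdir, "metadata.tsv"),
                 truth = file.path(outdir, "truth.json"),
                 sbs_spectra = spectra))
}

# place SBS records on the toy genome so that re-classification reproduces
# the spectra exactly: each context X[R>A]Y is planted at centre positions of
# forward-strand occurrences of the pyrimidine trinucleotide XRY
place_sbs_records <- function(spectra, genome) {
  contig <- names(genome)[1]
  gseq <- as.character(genome[[1]])
  catalog <- rownames(spectra)
  trinuc_of <- paste0(substr(catalog, 1, 1), substr(catalog, 3, 3),
                      substr(catalog, 7, 7))
  # positions (of centre base) of every trinucleotide actually needed
  pools <- list()
  for (tn in unique(trinuc_of[rowSums(spectra) > 0])) {
    hits <- gregexpr(paste0("(?=", tn, ")"), gseq, perl = TRUE)[[1]]
    if (hits[1] == -1) abort(paste0("trinucleotide ", tn, " absent from genome"))
    pools[[tn]] <- as.integer(hits) + 1L  # centre base, 1-based
  }
  out <- list()
  for (ci in colnames(spectra)) {
    used <- new.env(hash = TRUE)
    recs <- list()
    for (k in which(spectra[, ci] > 0)) {
      tn <- trinuc_of[k]
      need <- spectra[k, ci]
      avail <- pools[[tn]]
      avail <- avail[!vapply(as.character(avail), function(p) {
        !is.null(used[[p]])
      }, logical(1))]
      if (length(avail) < need) {
        abort(paste0("not enough sites for context ", catalog[k],
                     " (need ", need, ", have ", length(avail), ")"))
      }
      pos <- if (length(avail) == 1) avail else sample(avail, need)
      pos <- pos[seq_len(need)]
      for (p in pos) used[[as.character(p)]] <- TRUE
      recs[[catalog[k]]] <- tibble(
        clone_id = ci, chrom = contig, pos = as.numeric(pos),
        ref = substr(catalog[k], 3, 3), alt = substr(catalog[k], 5, 5),
        var_class = "SBS", sv_type = NA_character_, sv_len = NA_real_,
        filter = "PASS", consequence = NA_character_
      )
    }
    out[[ci]] <- bind_rows(recs)
  }
  bind_rows(out)
}
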
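#' Build a pipeline configuration
#'
#' Validates the inputs for [run_pipeline()]. Exactly one variant source
#' must be given: a directory of per-clone VCFs (`vcf_dir`, with `genome`
#' and `metadata`) or a `simulate` block (arguments for [sim_config()]).
#'
#' @param outdir Output directory.
#' @param vcf_dir Directory of per-clone VCFs named `<clone_id>.vcf`.
#' @param genome FASTA path (required with `vcf_dir`).
#' @param metadata Clone metadata TSV path (required with `vcf_dir`).
#' @param simulate Named list of [sim_config()] arguments.
#' @param signature_definitions Optional COSMIC-layout TSV; when absent a
#'   synthetic 4-signature model is used.
#' @param exposure_table Optional exposure TSV for prevalence-based
#'   signature selection.
#' @param exposure_types Cancer-type labels used for selection.
#' @param selection_threshold Prevalence threshold in `(0, 1]`.
#' @param drivers Optional driver-gene TSV.
#' @param reference_group Reference (healthy) group for comparisons.
#' @param alpha Significance level for reporting.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            vcf_dir = NULL, genome = NULL, metadata = NULL,
                            simulate = NULL,
                            signature_definitions = NULL,
                            exposure_table = NULL,
                            exposure_types = c("Liver-HCC",
                                               "Biliary-AdenoCA"),
                            selection_threshold = 0.10,
                            drivers = NULL,
                            reference_group = "healthy",
                            alpha = 0.05,
                            seed = 1) {
  if (is.null(vcf_dir) == is.null(simulate)) {
    abort("exactly one of vcf_dir or simulate must be given")
  }
  if (!is.null(vcf_dir) && (is.null(genome) || is.null(metadata))) {
    abort("vcf_dir input requires genome and metadata paths")
  }
  stopifnot(selection_threshold > 0, selection_threshold <= 1,
            alpha > 0, alpha < 1)
  structure(
    list(outdir = outdir, vcf_dir = vcf_dir, genome = genome,
         metadata = metadata, simulate = simulate,
         signature_definitions = signature_definitions,
         exposure_table = exposure_table, exposure_types = exposure_types,
         selection_threshold = selection_threshold, drivers = drivers,
         reference_group = reference_group, alpha = alpha,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> context classification -> signature
#' refitting -> burden statistics -> driver tallying from one
#' configuration. All outputs are written under `cfg$outdir` and listed in
#' `manifest.json` together with the seed, a configuration hash and md5
#' checksums; a rerun with the same configuration and seed reproduces every
#' file byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # --- input stage -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    cohort <- stage("simulate", simulate_cohort(scfg))
    ds <- stage("simulate",
                write_synthetic_dataset(cohort, outdir = file.path(cfg$outdir,
                                                                   "sim")))
    vcf_dir <- ds$vcf_dir
    genome_path <- ds$genome
    meta <- cohort$meta
  } else {
    vcf_dir <- cfg$vcf_dir
    genome_path <- cfg$genome
    meta <- stage("metadata", read_clone_metadata(cfg$metadata))
  }

  vcfs <- sort(list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE))
  if (length(vcfs) == 0) abort(paste0("no VCF files in ", vcf_dir))
  records <- stage("read_vcf", purrr::map(vcfs, function(v) {
    mutate(read_vcf_variants(v, pass_only = TRUE),
           clone_id = sub("\\.vcf$", "", basename(v)), .before = 1)
  }) |> bind_rows())
  n_pass <- nrow(records)

  # --- context stage -----------------------------------------------------
  genome <- stage("contexts", load_genome(genome_path))
  records <- stage("contexts", classify_variants(records, genome))
  classes <- intersect(c("SBS", "DBS", "INDEL", "SV"),
                       unique(records$var_class))
  spectra <- purrr::map(setNames(classes, classes), function(vc) {
    build_spectrum_matrix(records, vc, genome, clones = meta$clone_id)
  })
  for (vc in classes) {
    write_spectrum_tsv(spectra[[vc]],
                       file.path(cfg$outdir, paste0("spectrum_", vc, ".tsv")))
  }

  # --- signature stage ---------------------------------------------------
  model <- stage("signatures", if (!is.null(cfg$signature_definitions)) {
    read_signature_definitions(cfg$signature_definitions)
  } else {
    synthetic_signature_model(4, "SBS", seed = 1)
  })
  selected <- model$signatures
  if (!is.null(cfg$exposure_table)) {
    expo <- stage("signatures", read_exposure_table(cfg$exposure_table))
    selected <- stage("signatures",
                      select_signatures(expo, cfg$exposure_types,
                                        cfg$selection_threshold))
    selected <- intersect(model$signatures, selected)
    if (length(selected) == 0) {
      abort("signature selection removed every signature in the model")
    }
  }
  sub_model <- signature_model(
    sweep(model$definitions[, selected, drop = FALSE], 2,
          colSums(model$definitions[, selected, drop = FALSE]), "/")
  )
  fits <- NULL
  if ("SBS" %in% classes) {
    fits <- stage("signatures", fit_signatures(spectra[["SBS"]], sub_model))
    readr::write_tsv(fits, file.path(cfg$outdir, "signature_fits.tsv"))
  }

  # --- burden stats stage ------------------------------------------------
  totals <- records |>
    filter(!is.na(.data$context)) |>
    count(.data$clone_id, .data$var_class, name = "count")
  stats_tbl <- list(); comp_tbl <- list(); ctx_tbl <- list()
  for (vc in classes) {
    cnt <- totals |> filter(.data$var_class == vc) |>
      select("clone_id", "count")
    cnt <- meta |> select("clone_id") |>
      left_join(cnt, by = "clone_id") |>
      mutate(count = dplyr::coalesce(.data$count, 0L))
    fits_g <- purrr::map(unique(meta$group), function(g) {
      f <- fit_burden_regression(cnt, meta, group = g)
      mutate(dplyr::bind_cols(tidy(f), glance(f)[-1]), var_class = vc)
    })
    stats_tbl[[vc]] <- bind_rows(fits_g)
    ref <- cfg$reference_group
    if (ref %in% meta$group) {
      fit_ref <- fit_burden_regression(cnt, meta, group = ref)
      for (g in setdiff(unique(meta$group), ref)) {
        fit_g <- fit_burden_regression(cnt, meta, group = g)
        if (fit_g$var > 0 && fit_ref$var > 0 && fit_g$se > 0) {
          comp_tbl[[paste(vc, g)]] <-
            mutate(compare_groups(fit_g, fit_ref), var_class = vc)
        }
      }
      grp_map <- setNames(meta$group, meta$clone_id)
      for (g in setdiff(unique(meta$group), ref)) {
        keep <- colnames(spectra[[vc]])[grp_map[colnames(spectra[[vc]])]
                                        %in% c(g, ref)]
        ctx <- context_load_tests(spectra[[vc]][, keep, drop = FALSE],
                                  grp_map[keep])
        ctx_tbl[[paste(vc, g)]] <- mutate(ctx, var_class = vc, group = g,
                                          reference = ref)
      }
    }
  }
  readr::write_tsv(bind_rows(stats_tbl),
                   file.path(cfg$outdir, "burden_regressions.tsv"))
  if (length(comp_tbl) > 0) {
    readr::write_tsv(bind_rows(comp_tbl),
                     file.path(cfg$outdir, "group_comparisons.tsv"))
  }
  if (length(ctx_tbl) > 0) {
    readr::write_tsv(bind_rows(ctx_tbl),
                     file.path(cfg$outdir, "context_tests.tsv"))
  }

  # --- driver stage ------------------------------------------------------
  if (!is.null(cfg$drivers)) {
    genes <- stage("drivers", read_driver_genes(cfg$drivers))
    tallies <- stage("drivers", tally_driver_mutations(records, genes))
    readr::write_tsv(tallies, file.path(cfg$outdir, "driver_tallies.tsv"))
  }

  # --- manifest ----------------------------------------------------------
  outputs <- sort(setdiff(
    list.files(cfg$outdir, recursive = TRUE),
    "manifest.json"
  ))
  md5 <- tools::md5sum(file.path(cfg$outdir, outputs))
  cfg_for_hash <- cfg
  cfg_for_hash$outdir <- NULL
  manifest <- list(
    package = "mutaccum",
    version = as.character(utils::packageVersion("mutaccum")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_for_hash),
    n_pass_records = n_pass,
    n_classified = sum(!is.na(records$context)),
    spectrum_totals = purrr::map(spectra, function(m) sum(m)),
    outputs = as.list(setNames(unname(md5), outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
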
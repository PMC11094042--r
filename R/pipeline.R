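# Orchestration: a validated run configuration, the four analysis stages
# (simulate, benchmark, substitution matrix, structure annotation) and a
# reproducible report bundle with a checksummed manifest.

#' Build and validate a run configuration
#'
#' Either supply input paths (`scores`, `clinical`, optionally `regions`,
#' `confidence`, `proteins`, `structure`) or set `simulate = TRUE` with a
#' [cohort_config()] and a seed to generate the inputs first.
#'
#' @param scores,clinical,proteins,regions,confidence,structure Input paths
#'   (ignored when `simulate = TRUE`).
#' @param simulate Generate a synthetic cohort instead of reading inputs?
#' @param sim_config A [cohort_config()] (when simulating).
#' @param seed Seed for the simulation stage.
#' @param benign_cutoff,pathogenic_cutoff Threshold band edges.
#' @param ambiguous_policy `"ambiguous_as_error"` or `"ambiguous_excluded"`.
#' @param min_stars Minimum ClinVar review stars.
#' @param plddt_min pLDDT cutoff (applied when confidence data present).
#' @param region_type,region_mode Optional region restriction.
#' @param snv_restrict Restrict predicted frequencies and the substitution
#'   matrix to SNV-reachable substitutions?
#' @param annotate_layout PDB annotation layout (`"qb"` or `"snv_both"`).
#' @param sets Named list of accession vectors defining protein sets; the
#'   default single set `ALL` uses every accession.
#' @return A validated `run_config` object.
#' @export
run_config <- function(scores = NULL, clinical = NULL, proteins = NULL,
                       regions = NULL, confidence = NULL, structure = NULL,
                       simulate = FALSE, sim_config = cohort_config(),
                       seed = 1L,
                       benign_cutoff = 0.340, pathogenic_cutoff = 0.564,
                       ambiguous_policy = "ambiguous_as_error",
                       min_stars = 1L, plddt_min = 50,
                       region_type = NULL, region_mode = "inside",
                       snv_restrict = FALSE,
                       annotate_layout = "qb",
                       sets = NULL) {
  scheme <- threshold_scheme(benign_cutoff, pathogenic_cutoff)  # validates order
  if (!simulate) {
    for (p in c(scores, clinical, proteins, regions, confidence, structure)) {
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("input path does not exist: %s", p), call. = FALSE)
      }
    }
    if (is.null(scores) || is.null(clinical)) {
      stop("scores and clinical paths are required unless simulate = TRUE",
           call. = FALSE)
    }
  }
  structure(list(
    scores = scores, clinical = clinical, proteins = proteins,
    regions = regions, confidence = confidence, structure = structure,
    simulate = isTRUE(simulate), sim_config = sim_config,
    seed = as.integer(seed), scheme = scheme,
    ambiguous_policy = match.arg(ambiguous_policy,
                                 c("ambiguous_as_error", "ambiguous_excluded")),
    min_stars = as.integer(min_stars), plddt_min = plddt_min,
    region_type = region_type, region_mode = region_mode,
    snv_restrict = isTRUE(snv_restrict),
    annotate_layout = match.arg(annotate_layout, c("qb", "snv_both")),
    sets = sets
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; `sim_config` keys
#' mirror [cohort_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim_config)) do.call(cohort_config, y$sim_config)
    else cohort_config()
  y$sim_config <- NULL
  do.call(run_config, c(y, list(sim_config = sim)))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (optional) simulation; per-set benchmark rows;
#' substitution-matrix analysis with asymmetry/flip reports; structure
#' annotation of any supplied or generated structures. Writes a report
#' bundle into `out_dir` and a JSON manifest recording the configuration,
#' package version and an MD5 checksum of every output file. Outputs are
#' deterministic for fixed inputs and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(file.path(out_dir, basename(outputs)))
  })

  # -- load or simulate inputs
  if (config$simulate) {
    cohort <- generate_cohort(config$sim_config, config$seed)
    sim_dir <- file.path(out_dir, "simulated")
    write_cohort(cohort, sim_dir)
    scores <- cohort$scores
    clinical <- dplyr::filter(cohort$clinical, .data$stars >= config$min_stars)
    meta <- dplyr::select(cohort$proteins, "protein_acc", "length")
    regions <- if (nrow(cohort$regions)) cohort$regions else NULL
    confidence <- cohort$confidence
    structures <- cohort$structures
  } else {
    scores <- read_score_table(config$scores, dialect = "canonical")
    clinical <- read_clinical_table(config$clinical, min_stars = config$min_stars)
    meta <- if (!is.null(config$proteins)) {
      raw <- read_tsv_skip_comments(config$proteins)
      tibble::tibble(protein_acc = raw$protein_acc,
                     length = as.integer(raw$length))
    } else {
      # fall back to observed maximum position per accession
      dplyr::summarise(dplyr::group_by(scores, .data$protein_acc),
                       length = max(.data$position), .groups = "drop")
    }
    regions <- if (!is.null(config$regions)) read_region_table(config$regions)
      else NULL
    confidence <- if (!is.null(config$confidence))
      read_confidence(config$confidence) else NULL
    structures <- if (!is.null(config$structure)) {
      ln <- readr::read_lines(config$structure)
      stats::setNames(list(ln), sub("\\.pdb$", "", basename(config$structure)))
    } else NULL
  }

  # -- benchmark stage
  sets <- config$sets
  if (is.null(sets)) sets <- list(ALL = unique(meta$protein_acc))
  report <- purrr::imap_dfr(sets, function(accs, nm) {
    benchmark_protein_set(
      scores, clinical, meta, set = accs, set_name = nm,
      regions = regions, region_type = config$region_type,
      region_mode = config$region_mode,
      confidence = confidence, plddt_min = config$plddt_min,
      scheme = config$scheme, policy = config$ambiguous_policy,
      snv_restrict = config$snv_restrict
    )
  })
  report_path <- file.path(out_dir, "benchmark_report.tsv")
  readr::write_tsv(report, report_path, na = "", progress = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "benchmark_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, report_path, file.path(out_dir, "benchmark_report.json"))

  # -- substitution matrix stage
  restriction <- if (config$snv_restrict) "snv_only" else "all"
  sm <- mean_substitution_matrix(scores, restriction = restriction)
  sm_path <- file.path(out_dir, "substitution_matrix.tsv")
  write_subst_matrix(sm, sm_path)
  asym <- asymmetric_pairs(sm)
  flips <- label_flip_pairs(sm, config$scheme)
  pairs_path <- file.path(out_dir, "asymmetric_pairs.tsv")
  readr::write_tsv(asym, pairs_path, progress = FALSE)
  flips_path <- file.path(out_dir, "label_flips.tsv")
  readr::write_tsv(flips, flips_path, progress = FALSE)
  outputs <- c(outputs, sm_path, pairs_path, flips_path)

  # -- structure annotation stage
  annotated <- character(0)
  if (!is.null(structures)) {
    ann_dir <- file.path(out_dir, "annotated")
    dir.create(ann_dir, showWarnings = FALSE)
    for (nm in names(structures)) {
      acc <- sub("^AF-", "", sub("-F1.*$", "", nm))
      sc_acc <- dplyr::filter(scores, .data$protein_acc == !!acc)
      if (!nrow(sc_acc)) next
      prof <- residue_profile(sc_acc)
      ann <- annotate_structure(structures[[nm]], prof,
                                layout = config$annotate_layout)
      p <- file.path(ann_dir, paste0(nm, "_annotated.pdb"))
      write_pdb(ann, p)
      annotated <- c(annotated, p)
    }
    outputs <- c(outputs, annotated)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("missbench")),
    seed = config$seed,
    thresholds = unclass(config$scheme),
    ambiguous_policy = config$ambiguous_policy,
    min_stars = config$min_stars,
    snv_restrict = config$snv_restrict,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
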
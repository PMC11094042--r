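# Seeded synthetic cohorts: proteins with codon-backed sequences, score
# tables covering the SNV-reachable substitutions of each residue's codon,
# star-rated clinical labels with controllable label-truth concordance,
# TM-like region segments, pLDDT profiles with low-confidence stretches and
# CA-trace structures. Everything a benchmark run consumes, without
# downloads.

#' Configuration for a synthetic cohort
#'
#' A residue is "functionally critical" with probability `phi`; every
#' substitution at a critical residue is pathogenic in truth, all others
#' benign. Scores are drawn from the pathogenic/benign component of the
#' score model; clinical labels equal the truth with probability `kappa`.
#' pLDDT is Uniform(20, 49) inside disordered stretches and Uniform(60, 95)
#' elsewhere.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Uniform range of protein lengths (inclusive).
#' @param phi Fraction of functionally critical residues, in \[0, 1\].
#' @param score_model `"beta"` (default; bounded support matches \[0, 1\]
#'   scores) or `"gaussian"` (truncated to \[0, 1\]; admits a closed-form
#'   AUC oracle, see [expected_auc_gaussian()]).
#' @param beta_benign,beta_pathogenic Shape pairs `c(alpha, beta)` for the
#'   Beta score components.
#' @param mu_benign,mu_pathogenic,sigma_benign,sigma_pathogenic Gaussian
#'   component parameters.
#' @param clinical_rate Per-residue probability of carrying a clinically
#'   reported variant.
#' @param kappa Label–truth concordance, in \[0.5, 1\].
#' @param star_probs Probabilities of star counts 0–4.
#' @param tm_fraction Fraction of proteins given TM-like segments.
#' @param tm_len TM segment length (residues).
#' @param disorder_rate Expected disordered stretches per residue.
#' @param disorder_len_range Length range of a disordered stretch.
#' @param all_substitutions If `TRUE`, score every residue against all 19
#'   alternates (for all-substitution analyses) instead of only the
#'   SNV-reachable alternates of its codon.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_proteins = 20,
                          length_range = c(150, 400),
                          phi = 0.3,
                          score_model = c("beta", "gaussian"),
                          beta_benign = c(2, 8),
                          beta_pathogenic = c(8, 2),
                          mu_benign = 0.2, mu_pathogenic = 0.8,
                          sigma_benign = 0.15, sigma_pathogenic = 0.15,
                          clinical_rate = 0.2,
                          kappa = 0.9,
                          star_probs = c(0.05, 0.45, 0.35, 0.10, 0.05),
                          tm_fraction = 0.5,
                          tm_len = 21,
                          disorder_rate = 0.005,
                          disorder_len_range = c(20, 60),
                          all_substitutions = FALSE) {
  score_model <- match.arg(score_model)
  prob_ok <- function(p) is.numeric(p) && all(p >= 0) && all(p <= 1)
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] < 2 ||
      length_range[1] > length_range[2]) {
    stop("length_range must be c(min, max) with 2 <= min <= max", call. = FALSE)
  }
  if (!prob_ok(phi)) stop("phi must lie in [0,1]", call. = FALSE)
  if (!prob_ok(clinical_rate)) stop("clinical_rate must lie in [0,1]", call. = FALSE)
  if (!is.numeric(kappa) || kappa < 0.5 || kappa > 1) {
    stop("kappa must lie in [0.5, 1]", call. = FALSE)
  }
  if (length(star_probs) != 5 || !prob_ok(star_probs) ||
      abs(sum(star_probs) - 1) > 1e-8) {
    stop("star_probs must be 5 probabilities summing to 1", call. = FALSE)
  }
  if (!prob_ok(tm_fraction)) stop("tm_fraction must lie in [0,1]", call. = FALSE)
  if (sigma_benign <= 0 || sigma_pathogenic <= 0) {
    stop("sigmas must be positive", call. = FALSE)
  }
  if (any(c(beta_benign, beta_pathogenic) <= 0)) {
    stop("Beta shapes must be positive", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins), length_range = as.integer(length_range),
    phi = phi, score_model = score_model,
    beta_benign = beta_benign, beta_pathogenic = beta_pathogenic,
    mu_benign = mu_benign, mu_pathogenic = mu_pathogenic,
    sigma_benign = sigma_benign, sigma_pathogenic = sigma_pathogenic,
    clinical_rate = clinical_rate, kappa = kappa, star_probs = star_probs,
    tm_fraction = tm_fraction, tm_len = as.integer(tm_len),
    disorder_rate = disorder_rate,
    disorder_len_range = as.integer(disorder_len_range),
    all_substitutions = isTRUE(all_substitutions)
  ), class = "cohort_config")
}

# inverse-CDF sampling from a normal truncated to [0, 1]
rtruncnorm01 <- function(n, mu, sigma) {
  lo <- stats::pnorm(0, mu, sigma)
  hi <- stats::pnorm(1, mu, sigma)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sigma)
}

draw_scores <- function(n, pathogenic, config) {
  if (n == 0) return(numeric(0))
  if (config$score_model == "beta") {
    sh <- if (pathogenic) config$beta_pathogenic else config$beta_benign
    stats::rbeta(n, sh[1], sh[2])
  } else {
    mu <- if (pathogenic) config$mu_pathogenic else config$mu_benign
    sg <- if (pathogenic) config$sigma_pathogenic else config$sigma_benign
    rtruncnorm01(n, mu, sg)
  }
}

#' Closed-form AUC for two Gaussian score components
#'
#' For benign scores ~ N(mu_b, sigma_b^2) and pathogenic scores ~
#' N(mu_p, sigma_p^2), the probability that a pathogenic score exceeds a
#' benign one is `pnorm((mu_p - mu_b) / sqrt(sigma_b^2 + sigma_p^2))`.
#'
#' @param mu_b,mu_p Component means.
#' @param sigma_b,sigma_p Component standard deviations (positive).
#' @return The expected AUC.
#' @export
#' @examples
#' expected_auc_gaussian(0.2, 0.8, 0.15, 0.15)
expected_auc_gaussian <- function(mu_b, mu_p, sigma_b, sigma_p) {
  if (sigma_b <= 0 || sigma_p <= 0) {
    stop("sigmas must be positive", call. = FALSE)
  }
  stats::pnorm((mu_p - mu_b) / sqrt(sigma_b^2 + sigma_p^2))
}

#' Generate a toy CA-trace structure
#'
#' Writes one CA atom per residue on an ideal alpha-helical path (2.3 Å
#' radius, 100 degrees twist, 1.5 Å rise per residue), residues numbered
#' 1..L, occupancy 1.00 and the per-residue pLDDT in the B-factor column —
#' the AlphaFold monomer convention.
#'
#' @param sequence Amino-acid string or character vector of one-letter
#'   codes.
#' @param plddt Numeric vector of per-residue pLDDT values (recycled single
#'   value allowed; default 90).
#' @param chain Chain identifier (single character).
#' @return Character vector of PDB lines.
#' @export
generate_structure <- function(sequence, plddt = 90, chain = "A") {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (!length(aa)) stop("sequence must be non-empty", call. = FALSE)
  check_aa(aa, "sequence")
  L <- length(aa)
  plddt <- rep_len(plddt, L)
  theta <- (seq_len(L) - 1) * 100 * pi / 180
  x <- 2.3 * cos(theta)
  y <- 2.3 * sin(theta)
  z <- 1.5 * (seq_len(L) - 1)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(L), AA_THREE[aa], chain, seq_len(L), x, y, z, 1, plddt
  )
  c(lines, "TER", "END")
}

#' Generate a complete synthetic cohort
#'
#' Deterministic for a given `seed`: all randomness flows from one
#' `set.seed()` call. Each residue gets a sampled sense codon; its score
#' records cover exactly the SNV-reachable alternates of that codon (or all
#' 19 alternates when `config$all_substitutions`). Clinical labels equal the
#' residue-level ground truth with probability `config$kappa`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory).
#' @return A list with elements `proteins` (accession, length, sequence,
#'   plus the per-residue `truth` tibble), `scores`, `clinical`, `regions`,
#'   `confidence` (tibbles in the canonical column layouts), `structures`
#'   (named list of PDB line vectors), `config` and `seed`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is mandatory", call. = FALSE)
  }
  set.seed(as.integer(seed))
  accs <- sprintf("SYN%04d", seq_len(config$n_proteins))

  proteins <- list(); scores <- list(); clinical <- list()
  regions <- list(); confidence <- list(); structures <- list()
  truth_tabs <- list()

  for (k in seq_along(accs)) {
    acc <- accs[k]
    L <- sample(seq.int(config$length_range[1], config$length_range[2]), 1)
    codons <- sample(SENSE_CODONS, L, replace = TRUE)
    seq_aa <- unname(GENETIC_CODE_STD[codons])
    critical <- stats::runif(L) < config$phi

    # score records per residue
    alt_list <- lapply(seq_len(L), function(i) {
      if (config$all_substitutions) setdiff(AA_ORDER, seq_aa[i])
      else snv_reachable_from_codon(codons[i])
    })
    n_alt <- lengths(alt_list)
    pos_rep <- rep(seq_len(L), n_alt)
    sc <- tibble::tibble(
      protein_acc = acc,
      position = pos_rep,
      ref_aa = seq_aa[pos_rep],
      alt_aa = unlist(alt_list),
      pathogenic_truth = critical[pos_rep]
    )
    sc$score <- numeric(nrow(sc))
    sc$score[sc$pathogenic_truth] <- draw_scores(sum(sc$pathogenic_truth), TRUE, config)
    sc$score[!sc$pathogenic_truth] <- draw_scores(sum(!sc$pathogenic_truth), FALSE, config)
    sc$class <- classify_score(sc$score)

    # clinical sampling: one reported variant per sampled residue
    reported <- which(stats::runif(L) < config$clinical_rate & n_alt > 0)
    if (length(reported)) {
      alt_pick <- vapply(reported, function(i) {
        a <- alt_list[[i]]
        a[sample.int(length(a), 1)]
      }, character(1))
      truth_lab <- ifelse(critical[reported], "pathogenic", "benign")
      concord <- stats::runif(length(reported)) < config$kappa
      lab <- ifelse(concord, truth_lab,
                    ifelse(truth_lab == "pathogenic", "benign", "pathogenic"))
      clinical[[k]] <- tibble::tibble(
        protein_acc = acc,
        position = reported,
        ref_aa = seq_aa[reported],
        alt_aa = alt_pick,
        label = factor(lab, levels = c("benign", "pathogenic")),
        stars = sample(0:4, length(reported), replace = TRUE,
                       prob = config$star_probs)
      )
    }

    # TM-like segments
    if (stats::runif(1) < config$tm_fraction && L > config$tm_len + 2) {
      n_seg <- max(1L, round(L / 120))
      starts <- sort(sample.int(L - config$tm_len, n_seg))
      regions[[k]] <- tibble::tibble(
        protein_acc = acc,
        selection = sprintf("%d-%d", starts, starts + config$tm_len - 1L),
        region_type = "TM"
      )
    }

    # disordered stretches and pLDDT
    disordered <- rep(FALSE, L)
    n_str <- stats::rpois(1, config$disorder_rate * L)
    if (n_str > 0) {
      for (s in seq_len(n_str)) {
        len <- sample(seq.int(config$disorder_len_range[1],
                              config$disorder_len_range[2]), 1)
        st <- sample.int(max(1L, L - len + 1L), 1)
        disordered[st:min(L, st + len - 1L)] <- TRUE
      }
    }
    plddt <- ifelse(disordered, stats::runif(L, 20, 49), stats::runif(L, 60, 95))
    confidence[[k]] <- tibble::tibble(protein_acc = acc,
                                      position = seq_len(L), plddt = plddt)

    structures[[acc]] <- generate_structure(seq_aa, plddt)
    proteins[[k]] <- tibble::tibble(
      protein_acc = acc, length = L,
      sequence = paste(seq_aa, collapse = "")
    )
    truth_tabs[[k]] <- tibble::tibble(protein_acc = acc, position = seq_len(L),
                                      critical = critical, codon = codons)
    scores[[k]] <- sc
  }

  list(
    proteins = dplyr::bind_rows(proteins),
    truth = dplyr::bind_rows(truth_tabs),
    scores = dplyr::bind_rows(scores) |>
      dplyr::select(-"pathogenic_truth"),
    clinical = dplyr::bind_rows(clinical),
    regions = dplyr::bind_rows(regions),
    confidence = dplyr::bind_rows(confidence),
    structures = structures,
    config = config,
    seed = as.integer(seed)
  )
}

#' Write a generated cohort to canonical TSV and PDB files
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    scores = file.path(dir, "scores.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    regions = file.path(dir, "regions.tsv"),
    confidence = file.path(dir, "confidence.tsv"),
    proteins = file.path(dir, "proteins.tsv")
  )
  write_score_table(cohort$scores, paths[["scores"]])
  write_clinical_table(cohort$clinical, paths[["clinical"]])
  readr::write_tsv(cohort$regions, paths[["regions"]], progress = FALSE)
  readr::write_tsv(cohort$confidence, paths[["confidence"]], progress = FALSE)
  readr::write_tsv(dplyr::select(cohort$proteins, "protein_acc", "length"),
                   paths[["proteins"]], progress = FALSE)
  pdb_dir <- file.path(dir, "structures")
  dir.create(pdb_dir, showWarnings = FALSE)
  for (acc in names(cohort$structures)) {
    p <- file.path(pdb_dir, sprintf("AF-%s-F1.pdb", acc))
    write_pdb(cohort$structures[[acc]], p)
    paths[[paste0("structure_", acc)]] <- p
  }
  invisible(paths)
}
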
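# Joining predicted scores with clinical labels, residue-level restrictions
# (protein set, region membership, pLDDT confidence) and Table-style report
# rows with length-normalised mutation frequencies.

#' Join score records with clinical variants
#'
#' Inner join on (accession, position, alternate amino acid). Clinical
#' variants without a matching score are counted as unmatched; joins whose
#' reference amino acid disagrees between the two sides are rejected and
#' counted separately — never silently kept.
#'
#' @param scores Score tibble (see [read_score_table()]).
#' @param clinical Clinical tibble (see [read_clinical_table()]).
#' @return Tibble of joined variants (score columns + `label`, `stars`) with
#'   a `join_report` attribute
#'   `list(n_clinical, n_joined, n_unmatched, n_ref_mismatch)`.
#' @export
join_scores_labels <- function(scores, clinical) {
  hits <- dplyr::inner_join(
    clinical, scores,
    by = c("protein_acc", "position", "alt_aa"),
    suffix = c("_clinical", "_score"),
    relationship = "many-to-many"
  )
  mism <- hits$ref_aa_clinical != hits$ref_aa_score
  n_mismatch <- sum(mism)
  good <- hits[!mism, , drop = FALSE]
  out <- tibble::tibble(
    protein_acc = good$protein_acc,
    position = good$position,
    ref_aa = good$ref_aa_score,
    alt_aa = good$alt_aa,
    score = good$score,
    class = good$class,
    label = good$label,
    stars = good$stars
  )
  matched_key <- paste(out$protein_acc, out$position, out$ref_aa, out$alt_aa)
  clin_key <- paste(clinical$protein_acc, clinical$position, clinical$ref_aa,
                    clinical$alt_aa)
  n_unmatched <- sum(!(clin_key %in% matched_key))
  attr(out, "join_report") <- list(
    n_clinical = nrow(clinical),
    n_joined = nrow(out),
    n_unmatched = n_unmatched - n_mismatch,
    n_ref_mismatch = n_mismatch
  )
  out
}

region_positions <- function(regions, region_type = NULL) {
  if (!is.null(region_type)) {
    regions <- dplyr::filter(regions, .data$region_type %in% !!region_type)
  }
  regions |>
    dplyr::mutate(position = purrr::map(.data$selection, parse_selection)) |>
    tidyr::unnest("position") |>
    dplyr::distinct(.data$protein_acc, .data$position)
}

#' Keep items inside or outside annotated regions
#'
#' Operates at residue level: an item is inside when its position lies in any
#' region of the requested type for its accession (region boundaries are
#' inclusive). `mode = "outside"` keeps the complement *within annotated
#' accessions*; accessions with no region annotation of the requested type
#' are dropped under both modes and counted in the `subset_report` attribute.
#'
#' @param items Tibble with `protein_acc` and `position` columns.
#' @param regions Region tibble (see [read_region_table()]).
#' @param region_type Optional region type filter (e.g. `"TM"`).
#' @param mode `"inside"` or `"outside"`.
#' @return Filtered tibble, same columns as `items`.
#' @export
subset_residues <- function(items, regions, region_type = NULL,
                            mode = c("inside", "outside")) {
  mode <- match.arg(mode)
  pos <- region_positions(regions, region_type)
  annotated <- unique(pos$protein_acc)
  dropped_accs <- setdiff(unique(items$protein_acc), annotated)
  n_dropped <- sum(items$protein_acc %in% dropped_accs)
  kept <- dplyr::filter(items, .data$protein_acc %in% annotated)
  key <- paste(kept$protein_acc, kept$position)
  inside <- key %in% paste(pos$protein_acc, pos$position)
  out <- kept[if (mode == "inside") inside else !inside, , drop = FALSE]
  attr(out, "subset_report") <- list(
    n_dropped_unannotated = n_dropped,
    dropped_accessions = dropped_accs
  )
  out
}

#' Drop items on low-confidence residues
#'
#' Keeps items whose residue has pLDDT at or above `cutoff` (the boundary
#' value itself is kept; "lower than cutoff" is excluded). Items on residues
#' with no confidence entry are dropped and counted.
#'
#' @param items Tibble with `protein_acc` and `position`.
#' @param confidence Confidence tibble (see [read_confidence()]).
#' @param cutoff pLDDT threshold, default 50.
#' @return Filtered tibble with a `confidence_report` attribute.
#' @export
filter_by_confidence <- function(items, confidence, cutoff = 50) {
  conf_key <- paste(confidence$protein_acc, confidence$position)
  item_key <- paste(items$protein_acc, items$position)
  idx <- match(item_key, conf_key)
  plddt <- confidence$plddt[idx]
  n_no_conf <- sum(is.na(idx))
  keep <- !is.na(plddt) & plddt >= cutoff
  out <- items[keep, , drop = FALSE]
  attr(out, "confidence_report") <- list(
    n_dropped_low_plddt = sum(!is.na(plddt) & plddt < cutoff),
    n_dropped_no_confidence = n_no_conf
  )
  out
}

#' Length-normalised mutation frequencies
#'
#' Counts benign and pathogenic mutations per residue of the protein set:
#' clinical counts come from the labels, predicted counts from the three-way
#' class of each score (ambiguous predictions count in neither). Each count
#' is divided by the summed length of the proteins in `meta`. With
#' `snv_restrict`, predicted counts include only SNV-reachable
#' substitutions.
#'
#' @param clinical Clinical tibble.
#' @param scores Score tibble.
#' @param meta Protein metadata tibble with `protein_acc` and `length`.
#' @param scheme A [threshold_scheme()] for classifying scores.
#' @param snv_restrict Restrict predicted counts to SNV-reachable
#'   substitutions?
#' @return One-row tibble `f_cv_benign`, `f_cv_pathogenic`, `f_am_benign`,
#'   `f_am_pathogenic`.
#' @export
mutation_frequencies <- function(clinical, scores, meta,
                                 scheme = threshold_scheme(),
                                 snv_restrict = FALSE) {
  refd <- unique(c(clinical$protein_acc, scores$protein_acc))
  missing_len <- setdiff(refd, meta$protein_acc)
  if (length(missing_len)) {
    stop(sprintf("no protein length for accession(s): %s",
                 paste(missing_len, collapse = ", ")), call. = FALSE)
  }
  total_len <- sum(meta$length)
  if (total_len <= 0) stop("summed protein length must be positive", call. = FALSE)
  if (snv_restrict && nrow(scores)) {
    scores <- scores[is_snv_reachable(scores$ref_aa, scores$alt_aa), ,
                     drop = FALSE]
  }
  pred <- if (nrow(scores)) classify_score(scores$score, scheme) else factor()
  tibble::tibble(
    f_cv_benign = sum(clinical$label == "benign") / total_len,
    f_cv_pathogenic = sum(clinical$label == "pathogenic") / total_len,
    f_am_benign = sum(pred == "likely_benign") / total_len,
    f_am_pathogenic = sum(pred == "likely_pathogenic") / total_len
  )
}

#' Benchmark predicted scores against clinical labels for a protein set
#'
#' Runs the full evaluation for one protein set: restricts scores and
#' clinical variants to the set, optionally to residues inside/outside
#' annotated regions and to confidently predicted residues (in that fixed
#' order), joins the two sides, classifies scores, and reports the
#' Table-style row: counts, PPV/TPR/F1/aucROC/MCC and the four
#' length-normalised mutation frequencies.
#'
#' An empty joined subset (or single-class labels, for which the AUC is
#' undefined) yields flagged zeros in `degenerate`, not an error.
#'
#' @param scores,clinical,meta Input tibbles (scores, clinical labels,
#'   protein lengths).
#' @param set Optional character vector of accessions defining the protein
#'   set (default: every accession in `meta`).
#' @param set_name Label written into the report row.
#' @param regions,region_type,region_mode Optional region restriction (see
#'   [subset_residues()]).
#' @param confidence,plddt_min Optional confidence restriction (see
#'   [filter_by_confidence()]).
#' @param scheme A [threshold_scheme()].
#' @param policy Ambiguity policy for [build_confusion()].
#' @param snv_restrict Restrict predicted-frequency counts to SNV-reachable
#'   substitutions?
#' @return One-row tibble: `set`, `n_proteins`, `n_mutations` (joined
#'   variants before ambiguity handling), `n_evaluated` (in the confusion
#'   table), `ppv`, `tpr`, `f1`, `auc_roc`, `mcc`, `f_cv_benign`,
#'   `f_cv_pathogenic`, `f_am_benign`, `f_am_pathogenic`, `degenerate`.
#' @export
benchmark_protein_set <- function(scores, clinical, meta,
                                  set = NULL, set_name = "ALL",
                                  regions = NULL, region_type = NULL,
                                  region_mode = "inside",
                                  confidence = NULL, plddt_min = 50,
                                  scheme = threshold_scheme(),
                                  policy = "ambiguous_as_error",
                                  snv_restrict = FALSE) {
  if (!is.null(set)) {
    scores <- dplyr::filter(scores, .data$protein_acc %in% !!set)
    clinical <- dplyr::filter(clinical, .data$protein_acc %in% !!set)
    meta <- dplyr::filter(meta, .data$protein_acc %in% !!set)
  }
  if (!is.null(regions)) {
    scores <- subset_residues(scores, regions, region_type, region_mode)
    clinical <- subset_residues(clinical, regions, region_type, region_mode)
  }
  if (!is.null(confidence)) {
    scores <- filter_by_confidence(scores, confidence, plddt_min)
    clinical <- filter_by_confidence(clinical, confidence, plddt_min)
  }
  joined <- join_scores_labels(scores, clinical)
  flagged <- character(0)
  if (nrow(meta) && sum(meta$length) > 0) {
    freqs <- mutation_frequencies(clinical, scores, meta, scheme, snv_restrict)
  } else {
    freqs <- tibble::tibble(f_cv_benign = 0, f_cv_pathogenic = 0,
                            f_am_benign = 0, f_am_pathogenic = 0)
    flagged <- c(flagged, "frequencies")
  }
  if (nrow(joined)) {
    joined$prediction <- classify_score(joined$score, scheme)
    ct <- build_confusion(joined, truth = label, prediction = prediction,
                          policy = policy)
    mets <- compute_metrics(ct)
    if (!is.na(mets$degenerate)) {
      flagged <- strsplit(mets$degenerate, ",")[[1]]
    }
    auc <- if (dplyr::n_distinct(joined$label) == 2) {
      auc_roc(joined$score, joined$label)
    } else {
      flagged <- c(flagged, "auc_roc")
      0
    }
    n_eval <- ct$tp + ct$fp + ct$tn + ct$fn
  } else {
    mets <- tibble::tibble(ppv = 0, tpr = 0, f1 = 0, mcc = 0)
    auc <- 0
    n_eval <- 0L
    flagged <- c("ppv", "tpr", "f1", "mcc", "auc_roc")
  }
  tibble::tibble(
    set = set_name,
    n_proteins = dplyr::n_distinct(joined$protein_acc),
    n_mutations = nrow(joined),
    n_evaluated = n_eval,
    ppv = mets$ppv, tpr = mets$tpr, f1 = mets$f1, auc_roc = auc,
    mcc = mets$mcc,
    f_cv_benign = freqs$f_cv_benign,
    f_cv_pathogenic = freqs$f_cv_pathogenic,
    f_am_benign = freqs$f_am_benign,
    f_am_pathogenic = freqs$f_am_pathogenic,
    degenerate = if (length(flagged)) paste(unique(flagged), collapse = ",")
      else NA_character_
  )
}
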
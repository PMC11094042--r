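# Readers and writers for score tables, clinical variant tables, region and
# confidence annotations. All readers return tibbles keyed by protein
# accession and 1-based residue position.

CLASS_LEVELS <- c("likely_benign", "ambiguous", "likely_pathogenic")

#' Parse protein-variant tokens like "F508C"
#'
#' Decomposes substitution notation `<ref><position><alt>` into its parts.
#' Vectorised over `token`.
#'
#' @param token Character vector of substitution tokens, e.g. `"F508C"`.
#' @return A tibble with columns `ref_aa`, `position`, `alt_aa`.
#' @export
#' @examples
#' parse_protein_variant(c("F508C", "I1234V"))
parse_protein_variant <- function(token) {
  m <- stringr::str_match(token, "^([A-Za-z])([0-9]+)([A-Za-z])$")
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    stop(sprintf("malformed variant token '%s'", token[bad[1]]), call. = FALSE)
  }
  ref <- toupper(m[, 2])
  alt <- toupper(m[, 4])
  pos <- as.integer(m[, 3])
  nonstd <- which(!(ref %in% AA_ORDER) | !(alt %in% AA_ORDER))
  if (length(nonstd)) {
    stop(sprintf("non-standard amino-acid letter in token '%s'",
                 token[nonstd[1]]), call. = FALSE)
  }
  ident <- which(ref == alt)
  if (length(ident)) {
    stop(sprintf("identity substitution in token '%s' (ref must differ from alt)",
                 token[ident[1]]), call. = FALSE)
  }
  if (any(pos < 1L)) {
    stop(sprintf("position must be >= 1 in token '%s'",
                 token[which(pos < 1L)[1]]), call. = FALSE)
  }
  tibble::tibble(ref_aa = ref, position = pos, alt_aa = alt)
}

read_tsv_skip_comments <- function(path, dialect = NULL) {
  lines <- readr::read_lines(path)
  is_comment <- startsWith(lines, "#")
  # AlphaMissense-style files comment their header line ("#CHROM ..."):
  # recover it by stripping the leading '#'.
  hdr_idx <- which(is_comment &
                     grepl("\t", lines) &
                     grepl("CHROM|uniprot_id|protein_acc", lines))
  if (length(hdr_idx)) {
    lines[hdr_idx[1]] <- sub("^#", "", lines[hdr_idx[1]])
    is_comment[hdr_idx[1]] <- FALSE
  }
  lines <- lines[!is_comment & nzchar(lines)]
  readr::read_tsv(I(paste0(lines, collapse = "\n")),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

map_class_label <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("", "na", ".")] <- NA_character_
  out <- dplyr::case_match(
    x,
    c("likely_benign", "likely benign", "benign") ~ "likely_benign",
    c("ambiguous", "uncertain") ~ "ambiguous",
    c("likely_pathogenic", "likely pathogenic", "pathogenic") ~ "likely_pathogenic",
    .default = NA_character_
  )
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    stop(sprintf("unknown class label '%s'", x[which(unknown)[1]]), call. = FALSE)
  }
  factor(out, levels = CLASS_LEVELS)
}

#' Read a residue-level variant score table
#'
#' Supports three tab-separated dialects:
#' * `"canonical"` — this package's own format: columns `protein_acc`,
#'   `position`, `ref_aa`, `alt_aa`, `score`, `class`.
#' * `"aa_substitutions"` — columns `uniprot_id`, `protein_variant`
#'   (e.g. `"F508C"`), `am_pathogenicity`, `am_class`.
#' * `"hg38"` — as `aa_substitutions` plus genomic columns (`CHROM`, `POS`,
#'   `REF`, `ALT`, ...), which are carried through untouched with a
#'   `genome_` prefix and never interpreted.
#'
#' Lines starting with `#` are skipped (a commented header line such as
#' `#CHROM ...` is recognised and used). Scores are validated to lie in
#' \[0, 1\]; a violation fails with the offending row number.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"canonical"`, `"hg38"`, `"aa_substitutions"`.
#' @return A tibble of score records with columns `protein_acc`, `position`,
#'   `ref_aa`, `alt_aa`, `score`, `class` (factor with levels likely_benign,
#'   ambiguous, likely_pathogenic), plus any carried genomic columns.
#' @export
read_score_table <- function(path,
                             dialect = c("canonical", "hg38", "aa_substitutions")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_skip_comments(path)
  need <- switch(dialect,
    canonical = c("protein_acc", "position", "ref_aa", "alt_aa", "score"),
    hg38 = c("uniprot_id", "protein_variant", "am_pathogenicity"),
    aa_substitutions = c("uniprot_id", "protein_variant", "am_pathogenicity")
  )
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s dialect: missing required column(s): %s", dialect,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (dialect == "canonical") {
    out <- tibble::tibble(
      protein_acc = raw$protein_acc,
      position = as.integer(raw$position),
      ref_aa = toupper(raw$ref_aa),
      alt_aa = toupper(raw$alt_aa),
      score = as.numeric(raw$score),
      class = map_class_label(if ("class" %in% names(raw)) raw$class else
        rep(NA_character_, nrow(raw)))
    )
  } else {
    pv <- parse_protein_variant(raw$protein_variant)
    out <- tibble::tibble(
      protein_acc = raw$uniprot_id,
      position = pv$position,
      ref_aa = pv$ref_aa,
      alt_aa = pv$alt_aa,
      score = as.numeric(raw$am_pathogenicity),
      class = map_class_label(if ("am_class" %in% names(raw)) raw$am_class else
        rep(NA_character_, nrow(raw)))
    )
    if (dialect == "hg38") {
      genomic <- raw[, setdiff(names(raw),
                               c("uniprot_id", "protein_variant",
                                 "am_pathogenicity", "am_class", "transcript_id")),
                     drop = FALSE]
      names(genomic) <- paste0("genome_", tolower(names(genomic)))
      out <- dplyr::bind_cols(out, genomic)
    }
  }
  check_aa(out$ref_aa, "ref_aa")
  check_aa(out$alt_aa, "alt_aa")
  check_score_range(out$score, where = seq_len(nrow(out)))
  if (any(out$ref_aa == out$alt_aa)) {
    stop(sprintf("identity substitution at row %d",
                 which(out$ref_aa == out$alt_aa)[1]), call. = FALSE)
  }
  out
}

#' Write score records in the canonical TSV dialect
#'
#' @param scores Tibble of score records as returned by [read_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  out <- tibble::tibble(
    protein_acc = scores$protein_acc,
    position = scores$position,
    ref_aa = scores$ref_aa,
    alt_aa = scores$alt_aa,
    score = scores$score,
    class = as.character(scores$class)
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# ClinVar review-status -> star mapping (standard ClinVar semantics).
# Shipped as data so a caller can override it.
#' @rdname read_clinical_table
#' @export
clinvar_star_map <- c(
  "practice guideline" = 4L,
  "reviewed by expert panel" = 3L,
  "criteria provided, multiple submitters, no conflicts" = 2L,
  "criteria provided, single submitter" = 1L,
  "criteria provided, conflicting interpretations" = 1L,
  "criteria provided, conflicting classifications" = 1L,
  "no assertion criteria provided" = 0L,
  "no assertion provided" = 0L,
  "no classification provided" = 0L,
  "no classification for the single variant" = 0L
)

default_label_map <- function() {
  c("benign" = "benign",
    "likely benign" = "benign",
    "benign/likely benign" = "benign",
    "pathogenic" = "pathogenic",
    "likely pathogenic" = "pathogenic",
    "pathogenic/likely pathogenic" = "pathogenic")
}

#' Read a clinical variant table
#'
#' Accepts either the canonical dialect (columns `protein_acc`, `position`,
#' `ref_aa`, `alt_aa`, `label`, `stars`) or a ClinVar-export-like dialect with
#' columns `protein_acc`, `protein_change` (tokens like `"F508C"`, possibly
#' several comma-separated), `clinical_significance` and `review_status`
#' (matched case-insensitively, spaces allowed). Significance text is mapped
#' to the binary benign/pathogenic label via `label_map`; unmapped
#' significances are dropped and counted, never silently. Review status maps
#' to stars via [clinvar_star_map]; rows below `min_stars` are dropped and
#' counted. Duplicate (accession, position, ref, alt) rows keep the highest
#' star count.
#'
#' The returned tibble carries a `report` attribute:
#' `list(n_total, n_kept, n_dropped_label, n_dropped_stars, n_deduplicated,
#' dropped_labels)` with `n_total = n_kept + n_dropped_label + n_dropped_stars
#' + n_deduplicated`.
#'
#' @param path Path to a TSV file.
#' @param min_stars Minimum review-star count to keep (default 1).
#' @param label_map Named character vector mapping lower-case significance
#'   text to `"benign"` / `"pathogenic"`.
#' @param star_map Named integer vector mapping lower-case review-status text
#'   to star counts.
#' @return A tibble with columns `protein_acc`, `position`, `ref_aa`,
#'   `alt_aa`, `label` (factor benign/pathogenic), `stars`.
#' @export
read_clinical_table <- function(path, min_stars = 1L,
                                label_map = default_label_map(),
                                star_map = clinvar_star_map) {
  raw <- read_tsv_skip_comments(path)
  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  nm <- norm(names(raw))
  col <- function(...) {
    cands <- norm(c(...))
    hit <- which(nm %in% cands)
    if (length(hit)) names(raw)[hit[1]] else NA_character_
  }
  canonical <- all(c("protein_acc", "position", "ref_aa", "alt_aa", "label",
                     "stars") %in% nm)
  if (canonical) {
    df <- tibble::tibble(
      protein_acc = raw[[which(nm == "protein_acc")[1]]],
      position = as.integer(raw[[which(nm == "position")[1]]]),
      ref_aa = toupper(raw[[which(nm == "ref_aa")[1]]]),
      alt_aa = toupper(raw[[which(nm == "alt_aa")[1]]]),
      significance = tolower(raw[[which(nm == "label")[1]]]),
      stars = as.integer(raw[[which(nm == "stars")[1]]])
    )
  } else {
    acc_col <- col("protein_acc", "accession", "uniprot_id", "uniprot acc")
    chg_col <- col("protein_change", "protein change")
    sig_col <- col("clinical_significance", "clinical significance",
                   "clinical significance (last reviewed)")
    rev_col <- col("review_status", "review status")
    missing_cols <- c(acc = acc_col, change = chg_col, significance = sig_col,
                      review = rev_col)
    if (anyNA(missing_cols)) {
      stop(sprintf("clinical table: cannot map mandatory column(s): %s",
                   paste(names(missing_cols)[is.na(missing_cols)],
                         collapse = ", ")), call. = FALSE)
    }
    # one row per protein-change token
    df <- tibble::tibble(
      protein_acc = raw[[acc_col]],
      change = raw[[chg_col]],
      significance = tolower(sub("\\s*\\(.*\\)$", "", raw[[sig_col]])),
      review = tolower(raw[[rev_col]])
    ) |>
      tidyr::separate_rows("change", sep = "\\s*,\\s*") |>
      dplyr::filter(nzchar(.data$change))
    pv <- parse_protein_variant(df$change)
    stars <- unname(star_map[df$review])
    if (anyNA(stars)) {
      stop(sprintf("unknown review status '%s'", df$review[which(is.na(stars))[1]]),
           call. = FALSE)
    }
    df <- tibble::tibble(
      protein_acc = df$protein_acc,
      position = pv$position,
      ref_aa = pv$ref_aa,
      alt_aa = pv$alt_aa,
      significance = df$significance,
      stars = as.integer(stars)
    )
  }
  n_total <- nrow(df)
  df$label <- unname(label_map[df$significance])
  dropped_labels <- table(df$significance[is.na(df$label)])
  kept <- df[!is.na(df$label), , drop = FALSE]
  n_dropped_label <- n_total - nrow(kept)
  below <- kept$stars < min_stars
  n_dropped_stars <- sum(below)
  kept <- kept[!below, , drop = FALSE]
  pre_dedup <- nrow(kept)
  kept <- kept |>
    dplyr::arrange(dplyr::desc(.data$stars)) |>
    dplyr::distinct(.data$protein_acc, .data$position, .data$ref_aa,
                    .data$alt_aa, .keep_all = TRUE) |>
    dplyr::arrange(.data$protein_acc, .data$position, .data$alt_aa)
  n_dedup <- pre_dedup - nrow(kept)
  out <- tibble::tibble(
    protein_acc = kept$protein_acc,
    position = kept$position,
    ref_aa = kept$ref_aa,
    alt_aa = kept$alt_aa,
    label = factor(kept$label, levels = c("benign", "pathogenic")),
    stars = kept$stars
  )
  attr(out, "report") <- list(
    n_total = n_total,
    n_kept = nrow(out),
    n_dropped_label = n_dropped_label,
    n_dropped_stars = n_dropped_stars,
    n_deduplicated = n_dedup,
    dropped_labels = dropped_labels
  )
  out
}

#' Write clinical variants in the canonical TSV dialect
#'
#' @param clinical Tibble as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- dplyr::mutate(clinical, label = as.character(.data$label))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a region annotation table
#'
#' Regions are given per accession as a `selection` string — an inclusive
#' 1-based range (`"34-58"`), an explicit residue list (`"12,15,19"`) or a
#' mix — plus a free-text `region_type` (e.g. `TM`, `IBS`, `binding_site`).
#'
#' @param path Path to a TSV with columns `protein_acc`, `selection`,
#'   `region_type`.
#' @return A tibble with those three columns.
#' @export
read_region_table <- function(path) {
  raw <- read_tsv_skip_comments(path)
  need <- c("protein_acc", "selection", "region_type")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("region table: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  # validate every selection parses
  purrr::walk(raw$selection, parse_selection)
  tibble::as_tibble(raw[, need])
}

#' Read per-residue confidence (pLDDT)
#'
#' Accepts either a 3-column TSV (`protein_acc`, `position`, `plddt`) or an
#' AlphaFold-style PDB file whose B-factor column stores the per-residue
#' pLDDT; from a PDB, the value is taken from each residue's CA atom
#' (residues lacking a CA atom are skipped and counted in the `report`
#' attribute).
#'
#' @param path Path to a TSV or PDB file.
#' @param protein_acc Accession to assign when reading from a PDB; defaults
#'   to an `AF-<ACC>-F1` pattern found in the filename, else the basename.
#' @return A tibble with columns `protein_acc`, `position`, `plddt`
#'   (0–100).
#' @export
read_confidence <- function(path, protein_acc = NULL) {
  head_lines <- readr::read_lines(path, n_max = 50)
  is_pdb <- any(grepl("^(ATOM  |HETATM|HEADER|MODEL )", head_lines))
  if (is_pdb) {
    if (is.null(protein_acc)) {
      m <- stringr::str_match(basename(path), "AF-([A-Z0-9]+)-F1")[, 2]
      protein_acc <- if (!is.na(m)) m else
        sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
    }
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    atoms <- pdb$atom
    ca <- atoms[atoms$elety == "CA" & atoms$type %in% c("ATOM", "HETATM"), ]
    all_res <- unique(atoms$resno[atoms$type %in% c("ATOM", "HETATM")])
    skipped <- setdiff(all_res, ca$resno)
    out <- tibble::tibble(
      protein_acc = protein_acc,
      position = as.integer(ca$resno),
      plddt = as.numeric(ca$b)
    )
    attr(out, "report") <- list(n_skipped_no_ca = length(skipped),
                                skipped_positions = skipped)
  } else {
    raw <- read_tsv_skip_comments(path)
    need <- c("protein_acc", "position", "plddt")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      stop(sprintf("confidence table: missing column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    out <- tibble::tibble(
      protein_acc = raw$protein_acc,
      position = as.integer(raw$position),
      plddt = as.numeric(raw$plddt)
    )
  }
  bad <- which(!is.finite(out$plddt) | out$plddt < 0 | out$plddt > 100)
  if (length(bad)) {
    stop(sprintf("pLDDT out of [0,100] at row %d (value %s)", bad[1],
                 format(out$plddt[bad[1]])), call. = FALSE)
  }
  out
}

#' Parse a residue selection string
#'
#' Selections combine inclusive 1-based ranges and single residues, e.g.
#' `"461-472,1346-1362"` or `"12,15,19"`.
#'
#' @param selection A single selection string.
#' @return Sorted integer vector of unique positions.
#' @export
#' @examples
#' parse_selection("1-3,7")
parse_selection <- function(selection) {
  if (is.na(selection) || !nzchar(trimws(selection))) {
    stop("empty selection", call. = FALSE)
  }
  parts <- strsplit(trimws(selection), "\\s*,\\s*")[[1]]
  pos <- purrr::map(parts, function(p) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      se <- as.integer(strsplit(p, "-")[[1]])
      if (se[1] > se[2]) {
        stop(sprintf("invalid range '%s': start > end", p), call. = FALSE)
      }
      seq.int(se[1], se[2])
    } else if (grepl("^[0-9]+$", p)) {
      as.integer(p)
    } else {
      stop(sprintf("invalid selection part '%s'", p), call. = FALSE)
    }
  })
  pos <- sort(unique(unlist(pos)))
  if (any(pos < 1L)) stop("selection positions must be >= 1", call. = FALSE)
  pos
}
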
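# Single-nucleotide reachability between amino acids under the standard
# genetic code. Used to restrict means and frequencies to substitutions a
# single nucleotide variant (SNV) can actually produce.

#' Enumerate the nine single-nucleotide neighbours of a codon
#'
#' @param codon A single 3-letter codon over the DNA alphabet `A, C, G, T`.
#' @return Character vector of the 9 codons differing from `codon` at exactly
#'   one position.
#' @export
#' @examples
#' codon_neighbors("TTT")
codon_neighbors <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("`codon` must be a single 3-letter string", call. = FALSE)
  }
  codon <- toupper(codon)
  bases <- strsplit(codon, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop(sprintf("invalid codon '%s': letters must be A/C/G/T", codon),
         call. = FALSE)
  }
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), bases[p])) {
      alt <- bases
      alt[p] <- b
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

# Cache for the reachable-pair set; filled on first use.
.snv_cache <- new.env(parent = emptyenv())

#' Amino-acid substitutions reachable by a single nucleotide change
#'
#' An ordered pair (ref, alt) is SNV-reachable when some sense codon of `ref`
#' differs at exactly one nucleotide from a sense codon of `alt`. Stop codons
#' never participate; identity pairs are excluded. The relation is symmetric
#' because single-nucleotide changes are reversible.
#'
#' @return A tibble with columns `ref_aa` and `alt_aa`, one row per ordered
#'   reachable pair (150 rows under the standard code).
#' @export
#' @examples
#' nrow(snv_reachable_substitutions())
snv_reachable_substitutions <- function() {
  if (is.null(.snv_cache$pairs)) {
    pairs <- purrr::map_dfr(SENSE_CODONS, function(cod) {
      nb <- codon_neighbors(cod)
      nb <- nb[nb %in% SENSE_CODONS]
      ref <- GENETIC_CODE_STD[[cod]]
      alt <- unname(GENETIC_CODE_STD[nb])
      tibble::tibble(ref_aa = ref, alt_aa = alt[alt != ref])
    })
    .snv_cache$pairs <- dplyr::distinct(pairs) |>
      dplyr::arrange(.data$ref_aa, .data$alt_aa)
    .snv_cache$key <- paste(.snv_cache$pairs$ref_aa, .snv_cache$pairs$alt_aa)
  }
  .snv_cache$pairs
}

#' Test whether a substitution is reachable by a single nucleotide change
#'
#' Vectorised over `ref_aa` / `alt_aa`. Generic reachability: the test asks
#' whether any codon of the reference amino acid has a single-nucleotide
#' neighbour coding for the alternate. Use [snv_reachable_from_codon()] when
#' the actual codon is known.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes (standard 20).
#' @return Logical vector.
#' @export
#' @examples
#' is_snv_reachable("S", "C")  # TRUE:  TCT -> TGT
#' is_snv_reachable("F", "E")  # FALSE: all Phe/Glu codons differ at >1 site
is_snv_reachable <- function(ref_aa, alt_aa) {
  check_aa(ref_aa, "ref_aa")
  check_aa(alt_aa, "alt_aa")
  if (any(ref_aa == alt_aa)) {
    stop("identity substitutions are not allowed (ref_aa == alt_aa)",
         call. = FALSE)
  }
  snv_reachable_substitutions()  # ensure cache
  paste(ref_aa, alt_aa) %in% .snv_cache$key
}

#' Amino acids reachable from a specific codon by one nucleotide change
#'
#' Codon-specific reachability: returns the distinct amino acids coded by the
#' sense single-nucleotide neighbours of `codon`, excluding the codon's own
#' amino acid.
#'
#' @param codon A sense codon (3 letters, `A/C/G/T`).
#' @return Character vector of reachable alternate amino acids.
#' @export
snv_reachable_from_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- GENETIC_CODE_STD[codon]
  if (is.na(aa) || aa == "*") {
    stop(sprintf("'%s' is not a sense codon", codon), call. = FALSE)
  }
  nb <- codon_neighbors(codon)
  nb <- nb[nb %in% SENSE_CODONS]
  setdiff(unique(unname(GENETIC_CODE_STD[nb])), aa)
}
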
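# Shared fixture builders and independent oracles. Oracles deliberately use
# naive brute-force implementations, not the package's code paths.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

canonical_score_lines <- function(df) {
  c("protein_acc\tposition\tref_aa\talt_aa\tscore\tclass",
    sprintf("%s\t%d\t%s\t%s\t%s\t%s", df$protein_acc, df$position, df$ref_aa,
            df$alt_aa, format(df$score), df$class))
}

# The reconstructed single-protein benchmark fixture: 102 pathogenic
# variants of which 4 carry the printed mispredicted scores, and 17
# evaluated benign variants of which 4 carry the printed mispredicted
# scores (n = 119).
cftr2_fixture <- function() {
  tibble::tibble(
    protein_acc = "P13569",
    position = seq_len(119),
    ref_aa = "F",
    alt_aa = "C",
    score = c(rep(0.9, 98), 0.49, 0.39, 0.08, 0.5637,
              rep(0.1, 13), 0.87, 0.74, 0.35, 0.89),
    label = factor(rep(c("pathogenic", "benign"), c(102, 17)),
                   levels = c("benign", "pathogenic")),
    stars = 1L
  )
}

# O(n^2) pair-counting AUC oracle: P(pos > neg) + 0.5 P(pos == neg)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == "pathogenic"]
  neg <- scores[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# direct formula evaluation for confusion metrics
metrics_formula_oracle <- function(tp, fp, tn, fn) {
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(ppv = ppv, tpr = tpr, f1 = f1, mcc = mcc)
}

# exhaustive 61x9 codon-transition enumeration of SNV-reachable amino-acid
# pairs, written independently of the package internals
snv_pairs_oracle <- function() {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*", TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E", GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  sense <- names(code)[code != "*"]
  out <- character(0)
  for (cod in sense) {
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(cod, p, p) == b) next
      nb <- cod
      substr(nb, p, p) <- b
      if (!(nb %in% sense)) next
      if (code[[cod]] != code[[nb]]) {
        out <- c(out, paste0(code[[cod]], code[[nb]]))
      }
    }
  }
  sort(unique(out))
}

# Hanley-McNeil standard error of an empirical AUC
auc_se_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

tiny_pdb_lines <- function(bfac = c(30, 80)) {
  sprintf(
    "ATOM  %5d  CA  ALA A%4d      11.104  13.207   9.004  1.00%6.2f           C",
    seq_along(bfac), seq_along(bfac), bfac)
}
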
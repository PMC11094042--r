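test_that("protein-variant tokens decompose and validate", {
  out <- parse_protein_variant(c("F508C", "I1234V", "S912L"))
  expect_equal(out$ref_aa, c("F", "I", "S"))
  expect_equal(out$position, c(508L, 1234L, 912L))
  expect_equal(out$alt_aa, c("C", "V", "L"))

  expect_error(parse_protein_variant("F508F"), "identity")
  expect_error(parse_protein_variant("X508C"), "non-standard")
  expect_error(parse_protein_variant("508C"), "malformed")
  expect_error(parse_protein_variant("F508"), "malformed")
})

test_that("canonical score tables round-trip field by field", {
  df <- tibble::tibble(
    protein_acc = c("P1", "P1", "P2"),
    position = c(10L, 11L, 5L),
    ref_aa = c("F", "L", "C"),
    alt_aa = c("C", "P", "S"),
    score = c(0.87, 0.123456, 0),
    class = factor(c("likely_pathogenic", "ambiguous", "likely_benign"),
                   levels = levels(classify_score(0.5)))
  )
  path <- tempfile(fileext = ".tsv")
  write_score_table(df, path)
  back <- read_score_table(path, "canonical")
  expect_equal(as.data.frame(back), as.data.frame(df))
})

test_that("hg38 and aa_substitutions dialects agree on shared substitutions", {
  aa_path <- write_tmp(c(
    "# AlphaMissense-style comment",
    "uniprot_id\tprotein_variant\tam_pathogenicity\tam_class",
    "P13569\tF508C\t0.87\tlikely_pathogenic",
    "P13569\tI1234V\t0.08\tlikely_benign"))
  hg_path <- write_tmp(c(
    "# copyright-style comment line",
    "#CHROM\tPOS\tREF\tALT\tgenome\tuniprot_id\ttranscript_id\tprotein_variant\tam_pathogenicity\tam_class",
    "chr7\t117559593\tT\tG\thg38\tP13569\tENST1\tF508C\t0.87\tlikely_pathogenic",
    "chr7\t117642527\tA\tG\thg38\tP13569\tENST1\tI1234V\t0.08\tlikely_benign"))
  aa <- read_score_table(aa_path, "aa_substitutions")
  hg <- read_score_table(hg_path, "hg38")
  core <- c("protein_acc", "position", "ref_aa", "alt_aa", "score", "class")
  expect_equal(as.data.frame(hg[core]), as.data.frame(aa[core]))
  expect_equal(hg$position, c(508L, 1234L))
  expect_equal(hg$score, c(0.87, 0.08))
  # genomic columns carried but prefixed, never interpreted
  expect_true(all(c("genome_chrom", "genome_pos") %in% names(hg)))
})

test_that("score reader rejects bad rows with location", {
  bad <- write_tmp(c("protein_acc\tposition\tref_aa\talt_aa\tscore\tclass",
                     "P1\t1\tF\tC\t0.5\t",
                     "P1\t2\tF\tC\t1.2\t"))
  expect_error(read_score_table(bad, "canonical"), "row 2")
  nocol <- write_tmp(c("protein_acc\tposition\tref_aa\talt_aa",
                       "P1\t1\tF\tC"))
  expect_error(read_score_table(nocol, "canonical"), "score")
})

test_that("clinical reader maps labels and stars with full accounting", {
  path <- write_tmp(c(
    "protein_acc\tprotein_change\tclinical_significance\treview_status",
    "P1\tF508C\tPathogenic\tcriteria provided, single submitter",
    "P1\tL997F\tLikely benign\tcriteria provided, multiple submitters, no conflicts",
    "P1\tT1053I\tUncertain significance\treviewed by expert panel",
    "P1\tR117H\tPathogenic\tno assertion criteria provided",
    "P1\tG551D\tLikely pathogenic\tpractice guideline"))
  out <- read_clinical_table(path, min_stars = 1)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 3L)           # 5 total - 1 unmappable - 1 zero stars
  expect_equal(rep$n_total, 5L)
  expect_equal(rep$n_dropped_label, 1L)
  expect_equal(rep$n_dropped_stars, 1L)
  expect_equal(rep$n_kept + rep$n_dropped_label + rep$n_dropped_stars +
                 rep$n_deduplicated, rep$n_total)
  expect_named(rep$dropped_labels, "uncertain significance")
  expect_equal(sort(out$stars), c(1L, 2L, 4L))
  expect_setequal(as.character(out$label[out$position == 551]), "pathogenic")
})

test_that("duplicate clinical rows keep the highest star count", {
  path <- write_tmp(c(
    "protein_acc\tposition\tref_aa\talt_aa\tlabel\tstars",
    "P1\t10\tF\tC\tpathogenic\t1",
    "P1\t10\tF\tC\tpathogenic\t3"))
  out <- read_clinical_table(path, min_stars = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$stars, 3L)
  expect_equal(attr(out, "report")$n_deduplicated, 1L)
})

test_that("confidence reads from TSV and from CA records of a PDB", {
  tsv <- write_tmp(c("protein_acc\tposition\tplddt", "ACC\t10\t92.5"))
  out <- read_confidence(tsv)
  expect_equal(out$plddt, 92.5)
  expect_equal(out$position, 10L)

  pdb <- write_tmp(tiny_pdb_lines(c(30, 80)), ext = ".pdb")
  conf <- read_confidence(pdb, protein_acc = "TOY")
  expect_equal(conf$plddt, c(30, 80))
  expect_equal(conf$protein_acc, c("TOY", "TOY"))

  bad <- write_tmp(c("protein_acc\tposition\tplddt", "ACC\t10\t101"))
  expect_error(read_confidence(bad), "0,100")
})

test_that("selection strings parse ranges, lists and mixes", {
  expect_equal(parse_selection("34-58"), 34:58)
  expect_equal(parse_selection("12,15,19"), c(12L, 15L, 19L))
  expect_length(parse_selection("461-472,1346-1362"), 29L)
  expect_error(parse_selection("10-5"), "start > end")
  expect_error(parse_selection("a-b"), "invalid")
})
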
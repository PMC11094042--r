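mk_scores <- function(...) {
  tibble::tibble(...)
}

test_that("join matches on accession/position/alt and audits the rest", {
  scores <- tibble::tibble(protein_acc = "P1", position = 10L, ref_aa = "F",
                           alt_aa = "C", score = 0.9,
                           class = classify_score(0.9))
  clinical <- tibble::tibble(protein_acc = "P1", position = 10L, ref_aa = "F",
                             alt_aa = "C",
                             label = factor("pathogenic",
                                            levels = c("benign", "pathogenic")),
                             stars = 1L)
  j <- join_scores_labels(scores, clinical)
  expect_equal(nrow(j), 1L)
  expect_equal(j$score, 0.9)
  expect_equal(as.character(j$label), "pathogenic")

  # ref disagreement is rejected and counted, never silently kept
  clin2 <- dplyr::mutate(clinical, ref_aa = "L")
  j2 <- join_scores_labels(scores, clin2)
  expect_equal(nrow(j2), 0L)
  expect_equal(attr(j2, "join_report")$n_ref_mismatch, 1L)

  # 3 clinical rows, 2 with scores -> 2 joined, 1 unmatched
  clin3 <- dplyr::bind_rows(
    clinical,
    dplyr::mutate(clinical, position = 11L, ref_aa = "L", alt_aa = "P"),
    dplyr::mutate(clinical, position = 99L))
  sc3 <- dplyr::bind_rows(
    scores,
    tibble::tibble(protein_acc = "P1", position = 11L, ref_aa = "L",
                   alt_aa = "P", score = 0.2, class = classify_score(0.2)))
  j3 <- join_scores_labels(sc3, clin3)
  expect_equal(nrow(j3), 2L)
  expect_equal(attr(j3, "join_report")$n_unmatched, 1L)
})

test_that("region subsetting is inclusive and partitions annotated accessions", {
  items <- tibble::tibble(protein_acc = "P1", position = c(29L, 30L, 40L, 50L, 51L))
  regions <- tibble::tibble(protein_acc = "P1", selection = "30-50",
                            region_type = "TM")
  inside <- subset_residues(items, regions, "TM", "inside")
  outside <- subset_residues(items, regions, "TM", "outside")
  expect_equal(inside$position, c(30L, 40L, 50L))
  expect_equal(outside$position, c(29L, 51L))
  # exact partition: no loss, no duplication
  expect_setequal(c(inside$position, outside$position), items$position)

  # unannotated accessions drop from both modes and are counted
  items2 <- dplyr::bind_rows(items, tibble::tibble(protein_acc = "P2",
                                                   position = 40L))
  in2 <- subset_residues(items2, regions, "TM", "inside")
  expect_false("P2" %in% in2$protein_acc)
  expect_equal(attr(in2, "subset_report")$n_dropped_unannotated, 1L)
  out2 <- subset_residues(items2, regions, "TM", "outside")
  expect_false("P2" %in% out2$protein_acc)
})

test_that("confidence filter excludes residues below the cutoff only", {
  items <- tibble::tibble(protein_acc = "P1", position = 1:10)
  conf <- tibble::tibble(protein_acc = "P1", position = 1:10,
                         plddt = c(49.9, 50.0, 80, 20, 60, 45, 90, 30, 55, 100))
  kept <- filter_by_confidence(items, conf, cutoff = 50)
  expect_equal(kept$position, c(2L, 3L, 5L, 7L, 9L, 10L))  # 6 of 10 kept
  expect_equal(attr(kept, "confidence_report")$n_dropped_low_plddt, 4L)

  # residues with no confidence entry are dropped and counted
  kept2 <- filter_by_confidence(dplyr::bind_rows(
    items, tibble::tibble(protein_acc = "P1", position = 99L)), conf)
  expect_false(99L %in% kept2$position)
  expect_equal(attr(kept2, "confidence_report")$n_dropped_no_confidence, 1L)
})

test_that("mutation frequencies normalise by summed protein length", {
  meta <- tibble::tibble(protein_acc = c("P1", "P2"), length = c(100L, 150L))
  none <- mutation_frequencies(
    tibble::tibble(protein_acc = character(), position = integer(),
                   ref_aa = character(), alt_aa = character(),
                   label = factor(levels = c("benign", "pathogenic")),
                   stars = integer()),
    tibble::tibble(protein_acc = character(), position = integer(),
                   ref_aa = character(), alt_aa = character(),
                   score = double()),
    meta)
  expect_equal(unlist(none), c(f_cv_benign = 0, f_cv_pathogenic = 0,
                               f_am_benign = 0, f_am_pathogenic = 0))

  clinical <- tibble::tibble(
    protein_acc = "P1", position = 1:5, ref_aa = "A", alt_aa = "V",
    label = factor("benign", levels = c("benign", "pathogenic")), stars = 1L)
  f <- mutation_frequencies(clinical, none_scores <- tibble::tibble(
    protein_acc = character(), position = integer(), ref_aa = character(),
    alt_aa = character(), score = double()), meta)
  expect_equal(f$f_cv_benign, 5 / 250)

  # ambiguous predictions count in neither class
  scores <- tibble::tibble(
    protein_acc = "P2", position = 1:3, ref_aa = "S", alt_aa = "C",
    score = c(0.1, 0.45, 0.9))
  f2 <- mutation_frequencies(clinical[0, ], scores, meta)
  expect_equal(f2$f_am_benign, 1 / 250)
  expect_equal(f2$f_am_pathogenic, 1 / 250)

  # doubling lengths halves every frequency
  meta2 <- dplyr::mutate(meta, length = length * 2L)
  f3 <- mutation_frequencies(clinical, scores, meta2)
  f1 <- mutation_frequencies(clinical, scores, meta)
  expect_equal(unlist(f3), unlist(f1) / 2)

  expect_error(
    mutation_frequencies(clinical, scores, meta[1, ]),
    "P2")
})

test_that("SNV restriction and construction give exact predicted frequencies", {
  # every residue carries 6 SNV-reachable predictions, half benign half
  # pathogenic, none ambiguous -> f_am_benign = f_am_pathogenic = 3.0
  pairs <- snv_reachable_substitutions()
  refs <- c("L", "R")  # both have 6+ SNV partners
  recs <- purrr::map_dfr(seq_len(50), function(pos) {
    ref <- refs[(pos %% 2) + 1]
    alts <- pairs$alt_aa[pairs$ref_aa == ref][1:6]
    tibble::tibble(protein_acc = "P1", position = pos, ref_aa = ref,
                   alt_aa = alts, score = rep(c(0.1, 0.9), each = 3))
  })
  meta <- tibble::tibble(protein_acc = "P1", length = 50L)
  f <- mutation_frequencies(recs[0, ] |>
                              dplyr::mutate(label = factor(character(0),
                                levels = c("benign", "pathogenic")), stars = integer(0)),
                            recs, meta, snv_restrict = TRUE)
  expect_equal(f$f_am_benign, 3)
  expect_equal(f$f_am_pathogenic, 3)

  # a non-reachable substitution vanishes under snv_restrict
  recs2 <- dplyr::bind_rows(recs, tibble::tibble(
    protein_acc = "P1", position = 1L, ref_aa = "F", alt_aa = "E", score = 0.9))
  f2 <- mutation_frequencies(recs[0, ] |>
                               dplyr::mutate(label = factor(character(0),
                                 levels = c("benign", "pathogenic")), stars = integer(0)),
                             recs2, meta, snv_restrict = TRUE)
  expect_equal(f2$f_am_pathogenic, 3)
})

test_that("perfectly concordant cohorts benchmark to all-1 metrics", {
  cfg <- cohort_config(n_proteins = 4, length_range = c(60, 100), kappa = 1,
                       score_model = "gaussian", mu_benign = 0.05,
                       mu_pathogenic = 0.95, sigma_benign = 0.02,
                       sigma_pathogenic = 0.02, clinical_rate = 0.5)
  co <- generate_cohort(cfg, 99)
  r <- benchmark_protein_set(co$scores, co$clinical, co$proteins)
  expect_equal(r$ppv, 1)
  expect_equal(r$tpr, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$mcc, 1)
  expect_equal(r$auc_roc, 1)
  expect_equal(r$n_proteins, 4L)
})

test_that("restrictions only ever shrink the evaluated cohort", {
  cfg <- cohort_config(n_proteins = 6, length_range = c(80, 150),
                       clinical_rate = 0.4, tm_fraction = 1)
  co <- generate_cohort(cfg, 5)
  full <- benchmark_protein_set(co$scores, co$clinical, co$proteins)
  tm <- benchmark_protein_set(co$scores, co$clinical, co$proteins,
                              regions = co$regions, region_type = "TM",
                              region_mode = "inside")
  conf <- benchmark_protein_set(co$scores, co$clinical, co$proteins,
                                confidence = co$confidence, plddt_min = 50)
  expect_lte(tm$n_mutations, full$n_mutations)
  expect_lte(conf$n_mutations, full$n_mutations)

  # empty subset flags, does not throw
  empty <- benchmark_protein_set(co$scores, co$clinical, co$proteins,
                                 set = "NOPE")
  expect_equal(empty$n_mutations, 0L)
  expect_match(empty$degenerate, "mcc")
})

test_that("benchmark reports are byte-identical across identical runs", {
  cfg <- cohort_config(n_proteins = 3, length_range = c(50, 80))
  co <- generate_cohort(cfg, 17)
  r1 <- benchmark_protein_set(co$scores, co$clinical, co$proteins)
  r2 <- benchmark_protein_set(co$scores, co$clinical, co$proteins)
  p1 <- tempfile(); p2 <- tempfile()
  readr::write_tsv(r1, p1, progress = FALSE)
  readr::write_tsv(r2, p2, progress = FALSE)
  expect_identical(readLines(p1), readLines(p2))
})
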
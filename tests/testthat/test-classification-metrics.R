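test_that("classification partitions [0,1] with the published band edges", {
  s <- threshold_scheme()
  expect_equal(as.character(classify_score(0.08, s)), "likely_benign")
  expect_equal(as.character(classify_score(0.5637, s)), "ambiguous")
  expect_equal(as.character(classify_score(0.87, s)), "likely_pathogenic")
  # boundary values: lower edge enters the band, upper edge leaves it
  expect_equal(as.character(classify_score(0.340, s)), "ambiguous")
  expect_equal(as.character(classify_score(0.564, s)), "likely_pathogenic")
  # every score maps to exactly one category
  grid <- seq(0, 1, by = 0.001)
  cls <- classify_score(grid, s)
  expect_false(anyNA(cls))
  expect_error(classify_score(1.2, s), "out of")
  expect_error(threshold_scheme(0.6, 0.3), "benign_cutoff < pathogenic_cutoff")
})

test_that("confusion tables implement both ambiguity policies", {
  pairs <- tibble::tibble(
    label = rep(c("pathogenic", "pathogenic", "pathogenic",
                  "benign", "benign", "benign"),
                c(98, 3, 1, 3, 1, 13)),
    prediction = rep(c("likely_pathogenic", "ambiguous", "likely_benign",
                       "likely_pathogenic", "ambiguous", "likely_benign"),
                     c(98, 3, 1, 3, 1, 13))
  )
  err <- build_confusion(pairs, policy = "ambiguous_as_error")
  expect_equal(unclass(err)[c("tp", "fn", "fp", "tn")],
               list(tp = 98L, fn = 4L, fp = 4L, tn = 13L))
  expect_equal(err$tp + err$fp + err$tn + err$fn, nrow(pairs))

  exc <- build_confusion(pairs, policy = "ambiguous_excluded")
  expect_equal(unclass(exc)[c("tp", "fn", "fp", "tn")],
               list(tp = 98L, fn = 1L, fp = 3L, tn = 13L))
  expect_equal(exc$n_ambig_on_pathogenic_label, 3L)
  expect_equal(exc$n_ambig_on_benign_label, 1L)
  expect_equal(exc$tp + exc$fp + exc$tn + exc$fn +
                 exc$n_ambig_on_pathogenic_label + exc$n_ambig_on_benign_label,
               nrow(pairs))

  empty <- build_confusion(pairs[0, ])
  expect_equal(empty$tp + empty$fp + empty$tn + empty$fn, 0L)
})

test_that("metrics match direct formula evaluation on random confusion tables", {
  set.seed(11)
  for (i in 1:50) {
    cts <- sample(0:40, 4, replace = TRUE)
    ct <- confusion_table(cts[1], cts[2], cts[3], cts[4])
    got <- compute_metrics(ct)
    want <- metrics_formula_oracle(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got$ppv, want$ppv)
    expect_equal(got$tpr, want$tpr)
    expect_equal(got$f1, want$f1)
    expect_equal(got$mcc, want$mcc)
    expect_gte(got$mcc, -1)
    expect_lte(got$mcc, 1)
  }
})

test_that("degenerate confusion tables return flagged zeros, perfect gives 1", {
  perfect <- compute_metrics(confusion_table(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("ppv", "tpr", "f1", "mcc")]),
               c(ppv = 1, tpr = 1, f1 = 1, mcc = 1))
  expect_true(is.na(perfect$degenerate))

  # all-wrong classifier: marginals are all 1 so the MCC formula evaluates
  # cleanly to -1; PPV/TPR are true zeros, F1's denominator vanishes
  worst <- compute_metrics(confusion_table(0, 1, 0, 1))
  expect_equal(worst$mcc, -1)
  expect_equal(worst$ppv, 0)
  expect_equal(worst$tpr, 0)
  expect_match(worst$degenerate, "f1")

  none <- compute_metrics(confusion_table(0, 0, 0, 0))
  expect_equal(unlist(none[c("ppv", "tpr", "f1", "mcc")]),
               c(ppv = 0, tpr = 0, f1 = 0, mcc = 0))
  expect_match(none$degenerate, "mcc")
})

test_that("label permutation drives |MCC| toward zero", {
  set.seed(7)
  n <- 4000
  lab <- rep(c("benign", "pathogenic"), each = n / 2)
  pred <- sample(c("likely_benign", "likely_pathogenic"), n, replace = TRUE)
  d <- tibble::tibble(label = sample(lab), prediction = pred)
  m <- compute_metrics(build_confusion(d))
  expect_lt(abs(m$mcc), 3 / sqrt(n))
})

test_that("rank-based AUC equals the O(n^2) pair-counting oracle", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1),
                       rep(c("pathogenic", "benign"), each = 2)), 1)
  expect_equal(auc_roc(c(0.5, 0.5), c("pathogenic", "benign")), 0.5)
  set.seed(23)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), 2)   # rounding forces ties
    labels <- sample(c("benign", "pathogenic"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_roc(scores, labels), auc_pair_oracle(scores, labels))
  }
  expect_error(auc_roc(c(0.1, 0.2), c("benign", "benign")), "single class")
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(31)
  scores <- runif(100)
  labels <- sample(c("benign", "pathogenic"), 100, replace = TRUE)
  a <- auc_roc(scores, labels)
  expect_equal(auc_roc(qlogis(scores / 1.0001 + 1e-5), labels), a)
  flipped <- ifelse(labels == "benign", "pathogenic", "benign")
  expect_equal(a + auc_roc(scores, flipped), 1)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- round(runif(150), 2)
  labels <- sample(c("benign", "pathogenic"), 150, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("benign", "pathogenic"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_roc(scores, labels), ref)
})

test_that("confusion tidiers expose counts and metrics", {
  ct <- confusion_table(98, 4, 13, 4)
  td <- tidy(ct)
  expect_equal(td$count[td$cell == "tp"], 98)
  gl <- glance(ct)
  expect_equal(round(gl$mcc, 3), 0.725)
})
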
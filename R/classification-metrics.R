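# Three-way thresholding of pathogenicity scores, confusion tables against
# binary clinical labels, and the derived metrics (PPV, TPR, F1, MCC, aucROC).

#' Three-class threshold scheme for pathogenicity scores
#'
#' Scores below `benign_cutoff` are likely_benign; scores in
#' `[benign_cutoff, pathogenic_cutoff)` are ambiguous; scores at or above
#' `pathogenic_cutoff` are likely_pathogenic. Defaults are the published
#' AlphaMissense band edges (0.340 and 0.564).
#'
#' @param benign_cutoff,pathogenic_cutoff Band edges,
#'   `0 < benign_cutoff < pathogenic_cutoff < 1`.
#' @return An object of class `threshold_scheme`.
#' @export
#' @examples
#' classify_score(c(0.08, 0.5637, 0.87), threshold_scheme())
threshold_scheme <- function(benign_cutoff = 0.340, pathogenic_cutoff = 0.564) {
  if (!(is.numeric(benign_cutoff) && is.numeric(pathogenic_cutoff) &&
        benign_cutoff > 0 && pathogenic_cutoff < 1 &&
        benign_cutoff < pathogenic_cutoff)) {
    stop("cutoffs must satisfy 0 < benign_cutoff < pathogenic_cutoff < 1",
         call. = FALSE)
  }
  structure(list(benign_cutoff = benign_cutoff,
                 pathogenic_cutoff = pathogenic_cutoff),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("<threshold_scheme> benign < %.3f <= ambiguous < %.3f <= pathogenic\n",
              x$benign_cutoff, x$pathogenic_cutoff))
  invisible(x)
}

#' Classify scores into likely_benign / ambiguous / likely_pathogenic
#'
#' @param score Numeric vector of scores in \[0, 1\].
#' @param scheme A [threshold_scheme()].
#' @return Factor with levels `likely_benign`, `ambiguous`,
#'   `likely_pathogenic`.
#' @export
classify_score <- function(score, scheme = threshold_scheme()) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  check_score_range(score)
  out <- dplyr::case_when(
    score < scheme$benign_cutoff ~ "likely_benign",
    score < scheme$pathogenic_cutoff ~ "ambiguous",
    .default = "likely_pathogenic"
  )
  factor(out, levels = CLASS_LEVELS)
}

#' Build a confusion table from three-way predictions and binary labels
#'
#' Pathogenic is the positive class. Two policies govern ambiguous
#' predictions:
#' * `ambiguous_as_error` (default): an ambiguous call counts against the
#'   predictor — as a false negative when the clinical label is pathogenic
#'   and a false positive when it is benign.
#' * `ambiguous_excluded`: ambiguous calls are removed before counting and
#'   tallied separately per label side.
#'
#' @param data A data frame holding one row per evaluated variant.
#' @param truth Column with the binary clinical label
#'   (`"benign"`/`"pathogenic"`); tidy-eval, defaults to `label`.
#' @param prediction Column with the three-way predicted category; tidy-eval,
#'   defaults to `prediction`.
#' @param policy `"ambiguous_as_error"` or `"ambiguous_excluded"`.
#' @return An object of class `confusion_table` with counts `tp`, `fp`,
#'   `tn`, `fn`, `n_ambig_on_pathogenic_label`, `n_ambig_on_benign_label`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   label = c("pathogenic", "pathogenic", "benign"),
#'   prediction = c("likely_pathogenic", "ambiguous", "likely_benign"))
#' build_confusion(d)
build_confusion <- function(data, truth = label, prediction = prediction,
                            policy = c("ambiguous_as_error",
                                       "ambiguous_excluded")) {
  policy <- match.arg(policy)
  lab <- as.character(dplyr::pull(data, {{ truth }}))
  pred <- as.character(dplyr::pull(data, {{ prediction }}))
  if (!all(lab %in% c("benign", "pathogenic"))) {
    stop("truth column must be binary benign/pathogenic", call. = FALSE)
  }
  if (!all(pred %in% CLASS_LEVELS)) {
    stop("prediction column must hold likely_benign/ambiguous/likely_pathogenic",
         call. = FALSE)
  }
  amb_p <- sum(lab == "pathogenic" & pred == "ambiguous")
  amb_b <- sum(lab == "benign" & pred == "ambiguous")
  if (policy == "ambiguous_as_error") {
    tp <- sum(lab == "pathogenic" & pred == "likely_pathogenic")
    fn <- sum(lab == "pathogenic" & pred != "likely_pathogenic")
    tn <- sum(lab == "benign" & pred == "likely_benign")
    fp <- sum(lab == "benign" & pred != "likely_benign")
  } else {
    tp <- sum(lab == "pathogenic" & pred == "likely_pathogenic")
    fn <- sum(lab == "pathogenic" & pred == "likely_benign")
    tn <- sum(lab == "benign" & pred == "likely_benign")
    fp <- sum(lab == "benign" & pred == "likely_pathogenic")
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_ambig_on_pathogenic_label = amb_p,
                 n_ambig_on_benign_label = amb_b,
                 policy = policy),
            class = "confusion_table")
}

#' Construct a confusion table directly from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param n_ambig_on_pathogenic_label,n_ambig_on_benign_label Ambiguous
#'   tallies (used with the `ambiguous_excluded` policy).
#' @param policy Ambiguity policy recorded on the table.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn,
                            n_ambig_on_pathogenic_label = 0L,
                            n_ambig_on_benign_label = 0L,
                            policy = "ambiguous_as_error") {
  counts <- c(tp, fp, tn, fn, n_ambig_on_pathogenic_label,
              n_ambig_on_benign_label)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 n_ambig_on_pathogenic_label = as.integer(n_ambig_on_pathogenic_label),
                 n_ambig_on_benign_label = as.integer(n_ambig_on_benign_label),
                 policy = policy),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table policy=%s> TP=%d FP=%d TN=%d FN=%d (ambig on pathogenic=%d, on benign=%d)\n",
              x$policy, x$tp, x$fp, x$tn, x$fn,
              x$n_ambig_on_pathogenic_label, x$n_ambig_on_benign_label))
  invisible(x)
}

#' @export
tidy.confusion_table <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fp", "tn", "fn",
             "ambiguous_on_pathogenic", "ambiguous_on_benign"),
    count = c(x$tp, x$fp, x$tn, x$fn,
              x$n_ambig_on_pathogenic_label, x$n_ambig_on_benign_label)
  )
}

#' @export
glance.confusion_table <- function(x, ...) {
  compute_metrics(x)
}

#' Classification metrics from a confusion table
#'
#' Computes PPV (precision), TPR (recall), F1 and the Matthews correlation
#' coefficient. Any metric whose denominator vanishes is returned as 0 and
#' named in the `degenerate` column rather than raising, so sparse subsets
#' do not abort batch runs.
#'
#' @param ct A `confusion_table`.
#' @return One-row tibble with columns `ppv`, `tpr`, `f1`, `mcc`,
#'   `degenerate` (comma-joined names of zero-denominator metrics, `NA` if
#'   none).
#' @export
#' @examples
#' compute_metrics(confusion_table(tp = 98, fp = 4, tn = 13, fn = 4))
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  tp <- ct$tp; fp <- ct$fp; tn <- ct$tn; fn <- ct$fn
  flagged <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  ppv <- safe_div(tp, tp + fp, "ppv")
  tpr <- safe_div(tp, tp + fn, "tpr")
  f1 <- if (ppv + tpr == 0) {
    flagged <- c(flagged, "f1")
    0
  } else 2 * ppv * tpr / (ppv + tpr)
  mcc_den_sq <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (mcc_den_sq == 0) {
    flagged <- c(flagged, "mcc")
    0
  } else (tp * tn - fp * fn) / sqrt(mcc_den_sq)
  tibble::tibble(
    ppv = ppv, tpr = tpr, f1 = f1, mcc = mcc,
    degenerate = if (length(flagged)) paste(unique(flagged), collapse = ",")
      else NA_character_
  )
}

#' Area under the ROC curve (rank-based, midrank ties)
#'
#' Pathogenic is the positive class and higher scores mean more pathogenic.
#' The rank-sum formulation equals the probability that a random pathogenic
#' score exceeds a random benign score, plus half the probability of a tie.
#'
#' @param scores Numeric score vector.
#' @param labels Vector of `"benign"` / `"pathogenic"` labels, same length.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_roc(c(0.9, 0.8, 0.2, 0.1),
#'         c("pathogenic", "pathogenic", "benign", "benign"))
auc_roc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c("benign", "pathogenic"))) {
    stop("labels must be benign/pathogenic", call. = FALSE)
  }
  n_pos <- sum(labels == "pathogenic")
  n_neg <- sum(labels == "benign")
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: input contains a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "pathogenic"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
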
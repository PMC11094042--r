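# Ordered 20x20 mean-score substitution matrices, directional asymmetry and
# label-flip detection, and correlation with BLOSUM62.

#' Mean pathogenicity score per ordered amino-acid substitution
#'
#' Averages scores over all records of each ordered (ref, alt) pair — each
#' substitution instance counts once, with no per-protein reweighting. Under
#' `restriction = "snv_only"` records whose pair is not reachable by a
#' single nucleotide change are dropped first.
#'
#' @param scores Score tibble.
#' @param restriction `"all"` or `"snv_only"`.
#' @return An object of class `subst_matrix`: list with 20x20 `mean` and
#'   `count` matrices (rows = ref, cols = alt; `NA` mean where no records)
#'   and the `restriction` flag.
#' @export
mean_substitution_matrix <- function(scores, restriction = c("all", "snv_only")) {
  restriction <- match.arg(restriction)
  check_aa(scores$ref_aa, "ref_aa")
  check_aa(scores$alt_aa, "alt_aa")
  if (restriction == "snv_only" && nrow(scores)) {
    scores <- scores[is_snv_reachable(scores$ref_aa, scores$alt_aa), ,
                     drop = FALSE]
  }
  mean_m <- matrix(NA_real_, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  count_m <- matrix(0L, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  if (nrow(scores)) {
    agg <- scores |>
      dplyr::group_by(.data$ref_aa, .data$alt_aa) |>
      dplyr::summarise(mean = mean(.data$score), n = dplyr::n(),
                       .groups = "drop")
    idx <- cbind(match(agg$ref_aa, AA_ORDER), match(agg$alt_aa, AA_ORDER))
    mean_m[idx] <- agg$mean
    count_m[idx] <- agg$n
  }
  structure(list(mean = mean_m, count = count_m, restriction = restriction),
            class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf("<subst_matrix restriction=%s> %d/380 ordered cells defined\n",
              x$restriction, sum(!is.na(x$mean))))
  invisible(x)
}

#' @export
tidy.subst_matrix <- function(x, ...) {
  tibble::tibble(
    ref_aa = rep(AA_ORDER, times = 20),
    alt_aa = rep(AA_ORDER, each = 20),
    mean_score = as.vector(x$mean),
    n = as.vector(x$count)
  ) |>
    dplyr::filter(.data$ref_aa != .data$alt_aa)
}

#' Write a substitution matrix as a 20x20 TSV
#'
#' Rows are reference, columns alternate amino acids; undefined cells are
#' left empty.
#'
#' @param x A `subst_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subst_matrix <- function(x, path) {
  df <- as.data.frame(round(x$mean, 6))
  df <- cbind(ref_aa = rownames(df), df)
  readr::write_tsv(tibble::as_tibble(df), path, na = "", progress = FALSE)
  invisible(path)
}

#' Substitution pairs with directionally asymmetric mean scores
#'
#' Flags unordered pairs whose forward and reverse mean scores differ by at
#' least `min_delta` (inclusive). Each pair is reported once, oriented so
#' the higher-scoring direction comes first, sorted by delta descending.
#'
#' @param matrix A `subst_matrix`.
#' @param min_delta Minimum absolute mean difference (default 0.2).
#' @return Tibble with columns `aa_high`, `aa_low` (the flagged direction is
#'   `aa_high -> aa_low`), `forward_mean`, `reverse_mean`, `delta`.
#' @export
asymmetric_pairs <- function(matrix, min_delta = 0.2) {
  stopifnot(inherits(matrix, "subst_matrix"))
  m <- matrix$mean
  out <- purrr::map_dfr(seq_len(19), function(i) {
    purrr::map_dfr(seq.int(i + 1, 20), function(j) {
      fwd <- m[i, j]; rev <- m[j, i]
      if (is.na(fwd) || is.na(rev)) return(NULL)
      d <- abs(fwd - rev)
      # inclusive threshold, robust to floating-point representation of d
      if (d < min_delta - sqrt(.Machine$double.eps)) return(NULL)
      hi <- if (fwd >= rev) c(AA_ORDER[i], AA_ORDER[j]) else
        c(AA_ORDER[j], AA_ORDER[i])
      tibble::tibble(aa_high = hi[1], aa_low = hi[2],
                     forward_mean = max(fwd, rev),
                     reverse_mean = min(fwd, rev),
                     delta = d)
    })
  })
  if (!nrow(out)) {
    return(tibble::tibble(aa_high = character(), aa_low = character(),
                          forward_mean = double(), reverse_mean = double(),
                          delta = double()))
  }
  dplyr::arrange(out, dplyr::desc(.data$delta))
}

#' Substitution pairs whose mean-score label flips with direction
#'
#' A flip occurs when the mean score of one direction classifies as
#' likely_pathogenic while the reverse classifies as likely_benign; an
#' ambiguous classification on either side is not a flip.
#'
#' @param matrix A `subst_matrix`.
#' @param scheme A [threshold_scheme()].
#' @return Tibble with columns `aa_pathogenic_dir`, `aa_benign_dir` (the
#'   pathogenic direction is `aa_pathogenic_dir -> aa_benign_dir`),
#'   `pathogenic_mean`, `benign_mean`.
#' @export
label_flip_pairs <- function(matrix, scheme = threshold_scheme()) {
  stopifnot(inherits(matrix, "subst_matrix"))
  m <- matrix$mean
  purrr::map_dfr(seq_len(19), function(i) {
    purrr::map_dfr(seq.int(i + 1, 20), function(j) {
      fwd <- m[i, j]; rev <- m[j, i]
      if (is.na(fwd) || is.na(rev)) return(NULL)
      cls <- as.character(classify_score(c(fwd, rev), scheme))
      flip_fwd <- cls[1] == "likely_pathogenic" && cls[2] == "likely_benign"
      flip_rev <- cls[2] == "likely_pathogenic" && cls[1] == "likely_benign"
      if (!flip_fwd && !flip_rev) return(NULL)
      if (flip_fwd) {
        tibble::tibble(aa_pathogenic_dir = AA_ORDER[i],
                       aa_benign_dir = AA_ORDER[j],
                       pathogenic_mean = fwd, benign_mean = rev)
      } else {
        tibble::tibble(aa_pathogenic_dir = AA_ORDER[j],
                       aa_benign_dir = AA_ORDER[i],
                       pathogenic_mean = rev, benign_mean = fwd)
      }
    })
  })
}

#' Correlate substitution mean scores with BLOSUM62
#'
#' Each defined ordered cell contributes one point: x = BLOSUM62 score of
#' the unordered pair (the matrix is symmetric), y = mean pathogenicity
#' score of the ordered substitution. Pearson correlation (p-value from the
#' two-sided t distribution of r) and an ordinary least-squares line are
#' returned.
#'
#' @param matrix A `subst_matrix`.
#' @return An object of class `blosum_fit` with elements `r`, `p_value`,
#'   `slope`, `intercept`, `n`, and the point data; supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
blosum_correlation <- function(matrix) {
  stopifnot(inherits(matrix, "subst_matrix"))
  pts <- tidy(matrix) |>
    dplyr::filter(!is.na(.data$mean_score)) |>
    dplyr::mutate(blosum = BLOSUM62_MAT[cbind(.data$ref_aa, .data$alt_aa)])
  if (nrow(pts) < 3) {
    stop("blosum_correlation needs at least 3 defined cells", call. = FALSE)
  }
  ct <- stats::cor.test(pts$blosum, pts$mean_score, method = "pearson")
  fit <- stats::lm(mean_score ~ blosum, data = pts)
  structure(list(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = nrow(pts),
    data = pts
  ), class = "blosum_fit")
}

#' @export
print.blosum_fit <- function(x, ...) {
  cat(sprintf("<blosum_fit> r = %.3f (p = %.3g), slope = %.4f, intercept = %.4f, n = %d\n",
              x$r, x$p_value, x$slope, x$intercept, x$n))
  invisible(x)
}

#' @export
tidy.blosum_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "blosum"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.blosum_fit <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, slope = x$slope,
                 intercept = x$intercept, n = x$n)
}
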
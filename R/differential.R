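# per-metabolite two-group comparisons: group means +/- SD, fold change
# (larger-over-smaller convention with a direction flag), and a two-sided
# two-sample test

#' Two-sided per-metabolite group comparison
#'
#' Computes a two-sided p-value per metabolite for the difference between
#' the two sample groups.  `student_t` is the pooled-variance two-sample t
#' test (the package default), `welch_t` drops the equal-variance
#' assumption, and `mann_whitney` is the rank-sum test (exact null
#' distribution for combined n <= 12, normal approximation with tie
#' correction otherwise).
#'
#' When both groups have zero within-group variance the t statistic is
#' undefined: the p-value is 0 when the group means differ and `NA` (a
#' degenerate comparison, every value identical) when they coincide.
#'
#' @param X a [metabolite_matrix()].
#' @param groups per-sample group labels (default: taken from the matrix);
#'   exactly two distinct labels, each with at least two samples.
#' @param test which test to run.
#' @return named numeric vector of p-values, one per metabolite.
#' @export
two_group_test <- function(X, groups = NULL,
                           test = c("student_t", "welch_t", "mann_whitney")) {
  test <- match.arg(test)
  X <- as_metabolite_matrix(X)
  groups <- sample_groups(X, groups)
  lev <- unique(groups)
  if (length(lev) != 2)
    msig_stop(sprintf("exactly two group labels required, got: %s",
                      paste(lev, collapse = ", ")), "argument_error")
  A <- unclass(X)[, groups == lev[1], drop = FALSE]
  B <- unclass(X)[, groups == lev[2], drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2)
    msig_stop("each group needs at least 2 samples", "argument_error")
  if (test == "mann_whitney") {
    exact <- (nA + nB) <= 12
    p <- vapply(seq_len(nrow(X)), function(i)
      suppressWarnings(stats::wilcox.test(A[i, ], B[i, ], exact = exact,
                                          correct = TRUE)$p.value),
      numeric(1))
    return(stats::setNames(p, rownames(X)))
  }
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (test == "student_t") {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep.int(nA + nB - 2, nrow(X))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  p <- ifelse(se == 0,
              ifelse(mA == mB, NA_real_, 0),
              2 * stats::pt(-abs((mA - mB) / se), df))
  stats::setNames(p, rownames(X))
}

#' Per-metabolite fold-change table
#'
#' For each metabolite, reports the two group means and standard deviations,
#' the fold change as the ratio of the larger group mean over the smaller
#' (so decreases are reported as magnitudes > 1), a direction flag relative
#' to the reference group, the two-sided p-value from [two_group_test()]
#' and its Benjamini-Hochberg adjustment.
#'
#' A metabolite whose group mean is zero in either group gets `NA` fold
#' change and `undefined_ratio = TRUE`; the ratio is never patched with an
#' epsilon.
#'
#' @param X a [metabolite_matrix()].
#' @param groups per-sample group labels (default: taken from the matrix).
#' @param reference which group label is the reference for the `direction`
#'   flag (default: the first label encountered).
#' @param test test passed to [two_group_test()].
#' @return a data.frame (class `differential_table`) with columns
#'   `metabolite`, `mean_ref`, `sd_ref`, `mean_other`, `sd_other`,
#'   `fold_change`, `direction` (`"up"` when the reference group mean is
#'   larger, `"down"` when smaller, `"unchanged"` when equal),
#'   `undefined_ratio`, `p_value`, `adjusted_p`.  The reference and other
#'   group labels are carried in the `reference`/`other` attributes.
#' @export
fold_change <- function(X, groups = NULL, reference = NULL,
                        test = "student_t") {
  X <- as_metabolite_matrix(X)
  groups <- sample_groups(X, groups)
  lev <- unique(groups)
  if (length(lev) != 2)
    msig_stop(sprintf("exactly two group labels required, got: %s",
                      paste(lev, collapse = ", ")), "argument_error")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev)
    msig_stop(sprintf("`reference` must be one of: %s",
                      paste(lev, collapse = ", ")), "argument_error")
  other <- setdiff(lev, reference)
  R <- unclass(X)[, groups == reference, drop = FALSE]
  O <- unclass(X)[, groups == other, drop = FALSE]
  mR <- rowMeans(R); mO <- rowMeans(O)
  sdR <- apply(R, 1, stats::sd); sdO <- apply(O, 1, stats::sd)
  undef <- mR == 0 | mO == 0
  fc <- ifelse(undef, NA_real_, pmax(mR, mO) / pmin(mR, mO))
  direction <- ifelse(undef, NA_character_,
                      ifelse(mR > mO, "up", ifelse(mR < mO, "down", "unchanged")))
  p <- two_group_test(X, groups, test = test)
  tab <- data.frame(metabolite = rownames(X),
                    mean_ref = unname(mR), sd_ref = unname(sdR),
                    mean_other = unname(mO), sd_other = unname(sdO),
                    fold_change = unname(fc), direction = unname(direction),
                    undefined_ratio = unname(undef),
                    p_value = unname(p),
                    adjusted_p = unname(stats::p.adjust(p, method = "BH")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "reference") <- reference
  attr(tab, "other") <- other
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Write a differential table as TSV
#'
#' @param tab a `differential_table` from [fold_change()].
#' @param path output path.
#' @export
write_differential <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
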
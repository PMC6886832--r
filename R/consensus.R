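#' Consensus matrix over random NMF restarts
#'
#' Runs `n_runs` independently seeded factorizations at rank `k`, assigns
#' every sample to its maximum-loading signature in each run, and averages
#' the resulting connectivity matrices (entry (i, j) of a connectivity
#' matrix is 1 iff samples i and j share an assignment).  The consensus
#' entry is thus the co-clustering frequency of a sample pair across
#' restarts; a stable factorization yields entries near 0 or 1.
#'
#' @param X a [metabolite_matrix()] or nonnegative matrix.
#' @param k factorization rank.
#' @param n_runs number of random restarts (>= 1).
#' @param base_seed integer; run `r` uses seed `base_seed + r`.
#' @param ... further arguments passed to [nmf_factorize()] (objective,
#'   `max_iter`, `rel_tol`).
#' @return an object of class `consensus_result`: list with `k`, `consensus`
#'   (samples x samples, symmetric, unit diagonal), `cophenetic` (see
#'   [cophenetic_coefficient()]; `NA` for fewer than 3 samples), `n_runs`
#'   and `seeds`.
#' @export
consensus_matrix <- function(X, k, n_runs = 50L, base_seed = 0L, ...) {
  X <- as_metabolite_matrix(X)
  if (!is_count(n_runs)) msig_stop("`n_runs` must be >= 1", "argument_error")
  n <- ncol(X)
  seeds <- as.integer(base_seed) + seq_len(n_runs)
  C <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(nmf_factorize(X, k, seed = seeds[r], n_starts = 1L, ...),
                    error = function(e) {
                      msig_stop(sprintf("factorization failed in run %d: %s",
                                        r, conditionMessage(e)),
                                "consensus_run_error")
                    })
    a <- dominant_index(unclass(fit$loadings))
    C <- C + outer(a, a, "==")
  }
  C <- C / n_runs
  coph <- if (n >= 3) cophenetic_coefficient(C) else NA_real_
  structure(list(k = as.integer(k), consensus = C, cophenetic = coph,
                 n_runs = as.integer(n_runs), seeds = seeds),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d, %d samples, %d runs, cophenetic %s\n",
              x$k, nrow(x$consensus), x$n_runs,
              if (is.na(x$cophenetic)) "NA (degenerate)"
              else sprintf("%.4f", x$cophenetic)))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Converts the consensus matrix to the distance matrix `1 - consensus`,
#' builds an average-linkage dendrogram, and returns the Pearson correlation
#' between the original distances and the dendrogram-implied (cophenetic)
#' distances over all sample pairs.  A coefficient near 1 indicates that the
#' consensus structure is tree-like, i.e. the factorization clusters samples
#' stably.
#'
#' @param consensus a samples x samples consensus matrix (entries in
#'   `[0, 1]`, symmetric, unit diagonal) or a `consensus_result`.
#' @param linkage agglomeration method for the dendrogram.
#' @return the coefficient in `[-1, 1]`, or `NA_real_` when either distance
#'   set has zero variance (all pairwise distances equal), in which case the
#'   dendrogram is degenerate and no correlation is defined.
#' @export
cophenetic_coefficient <- function(consensus,
                                   linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (inherits(consensus, "consensus_result")) consensus <- consensus$consensus
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus))
    msig_stop("`consensus` must be a square matrix", "argument_error")
  if (nrow(consensus) < 3)
    msig_stop("cophenetic correlation needs at least 3 samples", "argument_error")
  if (max(abs(consensus - t(consensus))) > 1e-8 ||
      any(consensus < -1e-12) || any(consensus > 1 + 1e-12) ||
      any(abs(diag(consensus) - 1) > 1e-12))
    msig_stop("`consensus` must be symmetric with entries in [0,1] and unit diagonal",
              "validation_error")
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) return(NA_real_)
  hc <- stats::hclust(d, method = linkage)
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(NA_real_)
  stats::cor(d, cd)
}

#' Select the number of signatures by consensus stability
#'
#' Computes a [consensus_matrix()] for every candidate rank and chooses the
#' rank whose consensus matrix attains the highest cophenetic correlation
#' coefficient; ties are broken toward the smallest rank.  Rank 1 is
#' excluded by precondition (the coefficient is degenerate there).
#'
#' @param X a [metabolite_matrix()] or nonnegative matrix.
#' @param k_candidates integer vector of candidate ranks, each in
#'   `[2, n_samples]`.
#' @param n_runs restarts per candidate.
#' @param base_seed integer seed base shared across candidates.
#' @param ... passed on to [nmf_factorize()].
#' @return an object of class `rank_selection`: list with `k_candidates`,
#'   `cophenetic_by_k` (named numeric), `chosen_k` and `results` (the
#'   per-rank `consensus_result` objects, named by rank).
#' @export
select_rank <- function(X, k_candidates, n_runs = 50L, base_seed = 0L, ...) {
  X <- as_metabolite_matrix(X)
  if (length(k_candidates) == 0)
    msig_stop("`k_candidates` must not be empty", "argument_error")
  if (any(k_candidates < 2) || any(k_candidates > ncol(X)) ||
      any(k_candidates != round(k_candidates)))
    msig_stop(sprintf("candidate ranks must be integers in [2, %d]", ncol(X)),
              "argument_error")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  results <- lapply(k_candidates, function(k)
    consensus_matrix(X, k, n_runs = n_runs, base_seed = base_seed, ...))
  names(results) <- as.character(k_candidates)
  coph <- vapply(results, function(r) r$cophenetic, numeric(1))
  names(coph) <- as.character(k_candidates)
  if (all(is.na(coph)))
    msig_stop("cophenetic coefficient degenerate at every candidate rank",
              "degenerate_rank_selection")
  score <- ifelse(is.na(coph), -Inf, coph)
  chosen <- k_candidates[which.max(score)]  # first max = smallest rank on ties
  structure(list(k_candidates = k_candidates, cophenetic_by_k = coph,
                 chosen_k = chosen, results = results),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("rank_selection (cophenetic correlation by rank):\n")
  for (k in x$k_candidates) {
    co <- x$cophenetic_by_k[[as.character(k)]]
    cat(sprintf("  k = %d: %s%s\n", k,
                if (is.na(co)) "NA" else sprintf("%.4f", co),
                if (k == x$chosen_k) "  <- chosen" else ""))
  }
  invisible(x)
}

#' Write the per-rank cophenetic curve as a two-column TSV
#'
#' @param sel a `rank_selection`.
#' @param path output path.
#' @export
write_rank_curve <- function(sel, path) {
  utils::write.table(
    data.frame(k = sel$k_candidates,
               cophenetic = sprintf("%.17g", sel$cophenetic_by_k)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus matrix as TSV with sample identifiers
#'
#' @param cons a `consensus_result`.
#' @param path output path.
#' @export
write_consensus <- function(cons, path) {
  write_named_table(cons$consensus, "sample", path)
}
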
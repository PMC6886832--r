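# interpretation of fitted factors: dominant signatures, sample clustering,
# and per-signature top-metabolite lists

dominant_index <- function(L) {
  apply(L, 2, which.max)  # which.max takes the lowest index on ties
}

as_loading_matrix <- function(loadings) {
  if (inherits(loadings, "nmf_fit")) loadings <- loadings$loadings
  if (!is.matrix(loadings) || !is.numeric(loadings))
    msig_stop("expected a sample_weights, nmf_fit or numeric matrix",
              "argument_error")
  L <- unclass(loadings)
  if (is.null(rownames(L))) rownames(L) <- paste0("P", seq_len(nrow(L)))
  if (is.null(colnames(L))) colnames(L) <- sprintf("s%d", seq_len(ncol(L)))
  L
}

#' Predominant signature of each sample
#'
#' Assigns every sample the signature with the largest loading.  Ties are
#' broken toward the lowest signature index and flagged.
#'
#' @param loadings a [sample_weights()] matrix, an `nmf_fit`, or a plain
#'   signatures x samples matrix.
#' @return a data.frame with columns `sample`, `signature` (name),
#'   `signature_index` and `tie` (logical).
#' @export
dominant_signature <- function(loadings) {
  L <- as_loading_matrix(loadings)
  tot <- colSums(L)
  if (any(tot == 0))
    msig_stop(sprintf("sample(s) with all-zero loadings: %s",
                      paste(colnames(L)[tot == 0], collapse = ", ")),
              "undefined_dominance")
  idx <- dominant_index(L)
  tie <- apply(L, 2, function(v) sum(v == max(v)) > 1L)
  data.frame(sample = colnames(L), signature = rownames(L)[idx],
             signature_index = as.integer(idx), tie = unname(tie),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchically cluster samples by their signature make-up
#'
#' Each sample's loading column is first normalized to proportions (so the
#' clustering reflects relative signature contributions, not absolute
#' abundance scale), then samples are clustered by average linkage on the
#' chosen distance, and flat cluster labels are cut at `cut_k`.
#'
#' @param loadings a [sample_weights()] matrix, `nmf_fit`, or plain matrix.
#' @param distance `"correlation"` (1 - Pearson correlation between
#'   proportion profiles, the default) or `"euclidean"`.
#' @param cut_k number of flat clusters to cut, in `[1, n_samples]`.
#' @param groups optional per-sample group labels used to score
#'   cluster-group agreement.
#' @param linkage agglomeration method.
#' @return an object of class `cluster_assignment`: list with `hclust` (the
#'   merge tree), `flat_labels` (named integer vector), `purity_by_group`
#'   (fraction of each group's samples falling in its majority cluster;
#'   `NULL` without `groups`), `cophenetic` (correlation between the input
#'   distances and the tree's cophenetic distances; `NA` for < 3 samples)
#'   and the distance/linkage used.
#' @export
cluster_samples <- function(loadings, distance = c("correlation", "euclidean"),
                            cut_k = 2L, groups = NULL,
                            linkage = c("average", "complete", "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  L <- as_loading_matrix(loadings)
  n <- ncol(L)
  if (n < 2) msig_stop("need at least 2 samples to cluster", "argument_error")
  if (!is_count(cut_k) || cut_k > n)
    msig_stop(sprintf("`cut_k` must be in [1, %d]", n), "argument_error")
  tot <- colSums(L)
  if (any(tot == 0))
    msig_stop(sprintf("sample(s) with all-zero loadings: %s",
                      paste(colnames(L)[tot == 0], collapse = ", ")),
              "degenerate_profile")
  P <- sweep(L, 2, tot, "/")
  if (distance == "correlation") {
    sds <- apply(P, 2, stats::sd)
    if (any(sds == 0))
      msig_stop(sprintf("constant signature profile under correlation distance: %s",
                        paste(colnames(L)[sds == 0], collapse = ", ")),
                "degenerate_profile")
    D <- stats::as.dist(pmax(1 - stats::cor(P), 0))
  } else {
    D <- stats::dist(t(P))
  }
  hc <- stats::hclust(D, method = linkage)
  labels <- stats::cutree(hc, k = cut_k)
  purity <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (!is.null(names(groups))) groups <- groups[colnames(L)]
    if (length(groups) != n || anyNA(groups))
      msig_stop("group labels must cover every sample", "argument_error")
    purity <- vapply(unique(groups), function(g) {
      tab <- table(labels[groups == g])
      max(tab) / sum(tab)
    }, numeric(1))
  }
  coph <- if (n >= 3 && stats::sd(D) > 0) {
    cd <- stats::cophenetic(hc)
    if (stats::sd(cd) > 0) stats::cor(D, cd) else NA_real_
  } else NA_real_
  structure(list(hclust = hc, flat_labels = labels, purity_by_group = purity,
                 cophenetic = coph, distance = distance, linkage = linkage,
                 cut_k = as.integer(cut_k)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples, %s distance, %s linkage, cut at k = %d\n",
              length(x$flat_labels), x$distance, x$linkage, x$cut_k))
  if (!is.null(x$purity_by_group))
    cat("group purity:", paste(sprintf("%s = %.2f", names(x$purity_by_group),
                                       x$purity_by_group), collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param x a `cluster_assignment` or an `hclust` object.
#' @return a single Newick string with branch lengths derived from the merge
#'   heights.
#' @export
as_newick <- function(x) {
  hc <- if (inherits(x, "cluster_assignment")) x$hclust else x
  if (!inherits(hc, "hclust"))
    msig_stop("expected a cluster_assignment or hclust", "argument_error")
  ape::write.tree(ape::as.phylo(hc))
}

#' @rdname as_newick
#' @param path output file path.
#' @export
write_newick <- function(x, path) {
  writeLines(as_newick(x), path)
  invisible(path)
}

#' Top-weighted metabolites of a signature
#'
#' Orders a signature's metabolites by descending weight (ties broken by
#' metabolite identifier) and truncates by one of two rules:
#' `cumulative_mass` keeps the smallest prefix whose weights sum to at least
#' `threshold`; `weight_floor` keeps every metabolite with weight strictly
#' above `threshold`.
#'
#' @param signatures a [signature_set()] or `nmf_fit`.
#' @param signature signature name or column index.
#' @param rule truncation rule.
#' @param threshold rule parameter: mass in `(0, 1]` for `cumulative_mass`
#'   (default 0.5), floor `>= 0` for `weight_floor` (default 0).
#' @return a data.frame with columns `metabolite`, `weight` and
#'   `cumulative_weight`, in decreasing weight order.
#' @export
top_metabolites <- function(signatures, signature,
                            rule = c("cumulative_mass", "weight_floor"),
                            threshold = NULL) {
  rule <- match.arg(rule)
  if (inherits(signatures, "nmf_fit")) signatures <- signatures$signatures
  W <- unclass(signatures)
  if (is.character(signature)) {
    j <- match(signature, colnames(W))
    if (is.na(j))
      msig_stop(sprintf("unknown signature '%s'", signature), "lookup_error")
  } else {
    if (!is_count(signature) || signature > ncol(W))
      msig_stop("signature index out of range", "lookup_error")
    j <- as.integer(signature)
  }
  if (is.null(threshold)) threshold <- if (rule == "cumulative_mass") 0.5 else 0
  w <- W[, j]
  ids <- rownames(W)
  ord <- order(-w, ids)
  w <- w[ord]; ids <- ids[ord]
  cw <- cumsum(w)
  keep <- if (rule == "cumulative_mass") {
    if (threshold <= 0 || threshold > 1)
      msig_stop("`threshold` must lie in (0, 1] for cumulative_mass", "argument_error")
    seq_len(which(cw >= threshold - 1e-12)[1])
  } else {
    if (threshold < 0)
      msig_stop("`threshold` must be >= 0 for weight_floor", "argument_error")
    which(w > threshold)
  }
  data.frame(metabolite = ids[keep], weight = unname(w[keep]),
             cumulative_weight = unname(cw[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-signature top-metabolite tables as TSV
#'
#' @param signatures a [signature_set()] or `nmf_fit`.
#' @param dir output directory; one `top_<signature>.tsv` per signature.
#' @inheritParams top_metabolites
#' @export
write_top_metabolites <- function(signatures, dir,
                                  rule = "cumulative_mass", threshold = NULL) {
  if (inherits(signatures, "nmf_fit")) signatures <- signatures$signatures
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(colnames(signatures), function(s) {
    tab <- top_metabolites(signatures, s, rule = rule, threshold = threshold)
    p <- file.path(dir, sprintf("top_%s.tsv", s))
    utils::write.table(format(tab, digits = 17, scientific = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
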
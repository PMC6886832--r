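#' Nonnegative metabolite-abundance matrix
#'
#' Container for a metabolites x samples table of relative abundances
#' (e.g. integrated LC-MS/MS peak areas after upstream normalization),
#' with unique metabolite and sample identifiers and optional per-sample
#' group labels.  All downstream stages (factorization, rank selection,
#' clustering, differential analysis) take this class as input.
#'
#' @param values numeric matrix, metabolites in rows, samples in columns;
#'   every entry must be finite and >= 0.
#' @param metabolite_ids unique row identifiers (default: rownames).
#' @param sample_ids unique column identifiers (default: colnames).
#' @param groups optional character vector of per-sample group labels,
#'   either named by sample id or in column order.
#' @return An object of class `metabolite_matrix`: the numeric matrix with
#'   dimnames set and a `groups` attribute.
#' @examples
#' x <- metabolite_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("m1", "m2"), c("s1", "s2", "s3"))))
#' dim(x)
#' @export
metabolite_matrix <- function(values, metabolite_ids = rownames(values),
                              sample_ids = colnames(values), groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    msig_stop("`values` must be a numeric matrix", "validation_error")
  if (is.null(metabolite_ids) || is.null(sample_ids))
    msig_stop("metabolite and sample identifiers are required", "validation_error")
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (length(metabolite_ids) != nrow(values) || length(sample_ids) != ncol(values))
    msig_stop("identifier lengths do not match matrix dimensions", "validation_error")
  if (anyDuplicated(metabolite_ids))
    msig_stop(sprintf("duplicated metabolite identifier(s): %s",
                      paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", ")),
              "validation_error")
  if (anyDuplicated(sample_ids))
    msig_stop(sprintf("duplicated sample identifier(s): %s",
                      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
              "validation_error")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    msig_stop(sprintf("negative or non-finite entry at metabolite '%s', sample '%s'",
                      metabolite_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
              "validation_error")
  }
  dimnames(values) <- list(metabolite_ids, sample_ids)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (!is.null(names(groups))) {
      if (!setequal(names(groups), sample_ids))
        msig_stop("group label names do not match sample identifiers", "validation_error")
      groups <- groups[sample_ids]
    } else {
      if (length(groups) != length(sample_ids))
        msig_stop("group labels must have one entry per sample", "validation_error")
      names(groups) <- sample_ids
    }
  }
  structure(values, groups = groups, class = c("metabolite_matrix", "matrix", "array"))
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("metabolite_matrix: %d metabolites x %d samples\n", nrow(x), ncol(x)))
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (n = %d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

# Accept either a metabolite_matrix or a plain nonnegative matrix.
as_metabolite_matrix <- function(x) {
  if (inherits(x, "metabolite_matrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("met%0*d", nchar(nrow(x)), seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("s%d", seq_len(ncol(x)))
    return(metabolite_matrix(x))
  }
  msig_stop("expected a metabolite_matrix or numeric matrix", "argument_error")
}

sample_groups <- function(x, groups = NULL) {
  if (is.null(groups)) groups <- attr(x, "groups")
  if (is.null(groups))
    msig_stop("no group labels supplied and none attached to the matrix", "argument_error")
  groups <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(colnames(x))) groups <- groups[colnames(x)]
  if (length(groups) != ncol(x) || anyNA(groups))
    msig_stop("group labels must cover every sample", "argument_error")
  groups
}

#' Read a metabolite-abundance matrix from TSV
#'
#' Expected dialect: a header row of sample identifiers, first column holding
#' metabolite identifiers, tab-separated numeric cells.  This is the dialect
#' written by [write_metabolite_matrix()].
#'
#' @param path path to the matrix TSV.
#' @param groups_path optional path to a two-column TSV (`sample`, `group`)
#'   mapping sample identifiers to group labels.
#' @return a [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2)
    msig_stop("matrix TSV needs a metabolite-id column plus at least one sample column",
              "format_error")
  ids <- df[[1]]
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L)
  for (j in seq_len(ncol(df) - 1L)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(col))
    if (length(bad))
      msig_stop(sprintf("non-numeric cell at metabolite '%s', sample '%s': '%s'",
                        ids[bad[1]], names(df)[j + 1L], col[bad[1]]),
                "validation_error")
    vals[, j] <- num
  }
  colnames(vals) <- names(df)[-1]
  rownames(vals) <- ids
  groups <- if (!is.null(groups_path)) read_sample_groups(groups_path) else NULL
  metabolite_matrix(vals, groups = groups)
}

#' Write a metabolite-abundance matrix as TSV
#'
#' Values are printed with 17 significant digits so that a read/write round
#' trip reproduces the doubles exactly.
#'
#' @param x a [metabolite_matrix()] (or plain nonnegative matrix).
#' @param path output path for the matrix TSV.
#' @param groups_path optional path for the sample-to-group sidecar TSV
#'   (written only when the matrix carries group labels).
#' @export
write_metabolite_matrix <- function(x, path, groups_path = NULL) {
  x <- as_metabolite_matrix(x)
  out <- data.frame(metabolite = rownames(x),
                    apply(unclass(x), 2, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("metabolite", colnames(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- attr(x, "groups")
  if (!is.null(groups_path) && !is.null(g)) write_sample_groups(g, groups_path)
  invisible(path)
}

#' @rdname write_metabolite_matrix
#' @param groups named character vector of group labels (names = sample ids).
#' @export
write_sample_groups <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_metabolite_matrix
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character", sep = "\t")
  if (ncol(df) < 2) msig_stop("groups TSV needs columns `sample` and `group`", "format_error")
  stats::setNames(df[[2]], df[[1]])
}
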
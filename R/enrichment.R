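#' Pathway library
#'
#' A named collection of metabolite sets over a metabolite universe, as used
#' for overrepresentation analysis.
#'
#' @param pathways named list of character vectors (pathway name -> member
#'   metabolite names); members are de-duplicated, empty pathways rejected.
#' @param universe character vector of all metabolite names under
#'   consideration; defaults to the union of all pathway members.  Every
#'   pathway member must belong to the universe.
#' @return an object of class `pathway_library`: list with `pathways` and
#'   `universe`.
#' @export
pathway_library <- function(pathways, universe = NULL) {
  if (!is.list(pathways) || is.null(names(pathways)) ||
      any(!nzchar(names(pathways))))
    msig_stop("`pathways` must be a named list of metabolite-name vectors",
              "validation_error")
  if (anyDuplicated(names(pathways)))
    msig_stop("pathway names must be unique", "validation_error")
  pathways <- lapply(pathways, function(p) sort(unique(as.character(p))))
  if (any(lengths(pathways) == 0))
    msig_stop(sprintf("empty pathway(s): %s",
                      paste(names(pathways)[lengths(pathways) == 0], collapse = ", ")),
              "validation_error")
  members <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members)
  } else {
    universe <- unique(as.character(universe))
    out <- setdiff(members, universe)
    if (length(out))
      msig_stop(sprintf("pathway member(s) outside the universe: %s",
                        paste(utils::head(out, 5), collapse = ", ")),
                "validation_error")
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("pathway_library: %d pathways over %d metabolites (sizes %d-%d)\n",
              length(x$pathways), length(x$universe),
              min(lengths(x$pathways)), max(lengths(x$pathways))))
  invisible(x)
}

#' Read a pathway library from a GMT file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name`, `description`, then one or more member names.
#'
#' @param path path to the GMT file.
#' @param universe optional metabolite universe; defaults to the union of
#'   all members.
#' @return a [pathway_library()]; pathway descriptions are kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  paths <- list(); descs <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      msig_stop(sprintf("GMT line %d has fewer than 3 fields", i), "format_error")
    paths[[f[1]]] <- f[-(1:2)]
    descs[f[1]] <- f[2]
  }
  lib <- pathway_library(paths, universe = universe)
  attr(lib, "descriptions") <- descs
  lib
}

#' Write a pathway library in GMT format
#'
#' @param lib a [pathway_library()].
#' @param path output path.
#' @param descriptions optional named character vector of per-pathway
#'   descriptions (default: the library's stored descriptions, else `"na"`).
#' @export
write_gmt <- function(lib, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(lib, "descriptions")
  lines <- vapply(names(lib$pathways), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm])) descriptions[nm] else "na"
    paste(c(nm, d, lib$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Exact overrepresentation p-value
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a hit set and a pathway when `|hits|` metabolites are
#' drawn without replacement from a universe containing `|pathway|`
#' successes (one-sided Fisher exact test).
#'
#' @param hits character vector of hit metabolites (must lie in `universe`).
#' @param pathway character vector of pathway members (must lie in
#'   `universe`).
#' @param universe character vector of all measurable metabolites.
#' @return the exact p-value `P(overlap >= observed)`.
#' @examples
#' # 5 hits, pathway of 5, universe of 10, full overlap: 1 / choose(10, 5)
#' ora_test(letters[1:5], letters[1:5], letters[1:10])
#' @export
ora_test <- function(hits, pathway, universe) {
  hits <- unique(as.character(hits))
  pathway <- unique(as.character(pathway))
  universe <- unique(as.character(universe))
  bad <- c(setdiff(hits, universe), setdiff(pathway, universe))
  if (length(bad))
    msig_stop(sprintf("member(s) outside the universe: %s",
                      paste(utils::head(unique(bad), 5), collapse = ", ")),
              "membership_error")
  overlap <- length(intersect(hits, pathway))
  stats::phyper(overlap - 1, length(pathway),
                length(universe) - length(pathway), length(hits),
                lower.tail = FALSE)
}

#' Pathway overrepresentation of a signature's top metabolites
#'
#' Tests each pathway in a library for overrepresentation among the
#' top-weighted metabolites of one signature (hypergeometric upper tail),
#' with Benjamini-Hochberg adjustment across pathways.  The test universe is
#' the intersection of the library universe with the metabolites of the
#' signature set (metabolites never measured cannot be hits); pathways are
#' restricted to that universe.
#'
#' @param signatures a [signature_set()] or `nmf_fit`.
#' @param signature signature name or index to test.
#' @param library a [pathway_library()].
#' @param rule,threshold top-metabolite rule passed to [top_metabolites()].
#' @param mode `"all"` tests every top metabolite of the signature;
#'   `"exclusive"` removes metabolites that are also top metabolites of the
#'   signature named in `other` before testing.
#' @param other the contrasting signature (required for
#'   `mode = "exclusive"`).
#' @return a data.frame (class `enrichment_table`) with one row per pathway:
#'   `pathway`, `overlap`, `pathway_size`, `hits_size`, `universe_size`,
#'   `p_value`, `adjusted_p`, sorted by ascending p (ties by pathway name).
#' @export
enrich_signature <- function(signatures, signature, library,
                             rule = "cumulative_mass", threshold = NULL,
                             mode = c("all", "exclusive"), other = NULL) {
  mode <- match.arg(mode)
  if (inherits(signatures, "nmf_fit")) signatures <- signatures$signatures
  if (!inherits(library, "pathway_library"))
    msig_stop("`library` must be a pathway_library", "argument_error")
  universe <- intersect(library$universe, rownames(signatures))
  if (length(universe) == 0)
    msig_stop("no overlap between library universe and signature metabolites",
              "membership_error")
  hits <- top_metabolites(signatures, signature, rule = rule,
                          threshold = threshold)$metabolite
  if (mode == "exclusive") {
    if (is.null(other))
      msig_stop("`other` signature is required for mode = 'exclusive'",
                "argument_error")
    hits <- setdiff(hits, top_metabolites(signatures, other, rule = rule,
                                          threshold = threshold)$metabolite)
  }
  hits <- intersect(hits, universe)
  if (length(hits) == 0)
    msig_stop("no top metabolites resolvable against the library universe",
              "empty_hits")
  rows <- lapply(names(library$pathways), function(nm) {
    pw <- intersect(library$pathways[[nm]], universe)
    data.frame(pathway = nm,
               overlap = length(intersect(hits, pw)),
               pathway_size = length(pw),
               hits_size = length(hits),
               universe_size = length(universe),
               p_value = ora_test(hits, pw, universe),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- tab[order(tab$p_value, tab$pathway), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Write an enrichment table as TSV
#'
#' @param tab an `enrichment_table`.
#' @param path output path.
#' @export
write_enrichment <- function(tab, path) {
  out <- as.data.frame(tab)
  out$p_value <- sprintf("%.17g", out$p_value)
  out$adjusted_p <- sprintf("%.17g", out$adjusted_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
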
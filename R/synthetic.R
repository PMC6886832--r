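#' Configuration for a synthetic two-group metabolomics study
#'
#' Describes the planted structure of a simulated metabolite-abundance study:
#' a small number of nonnegative metabolite signatures, one dominant signature
#' per sample group, multiplicative log-normal noise, and optional planted
#' per-metabolite group fold changes.  The defaults emulate the design this
#' package is built around: 280 metabolites measured in two groups of six
#' samples, mixed from four signatures of which one dominates each group,
#' with three metabolites carrying planted fold changes of 4.31, 3.26 and
#' 3.16 (group A over group B).
#'
#' @param n_metabolites number of metabolites (rows).
#' @param n_per_group named integer vector of samples per group; names are
#'   the group labels (first group is the "A"/reference group to which
#'   planted fold-change multipliers are applied).
#' @param n_signatures number of planted signatures.
#' @param group_signature_map named integer vector assigning each group its
#'   dominant signature index.  Default: one distinct signature per group
#'   (indices 2, 4, ... when enough signatures exist, mirroring a design in
#'   which the remaining signatures are shared background).
#' @param dominance fraction in (0.5, 1] of each sample's total loading
#'   carried by its group's dominant signature.
#' @param signature_sparsity fraction in (0, 1] of metabolites given
#'   non-negligible weight in each signature.
#' @param noise_cv coefficient of variation (>= 0) of the multiplicative
#'   log-normal noise (median 1) applied entrywise.
#' @param sample_scale_cv coefficient of variation (>= 0) of the per-sample
#'   total-loading scale factor; set to 0 for equal per-sample totals.
#' @param loading_scale expected total loading per sample (abundance units).
#' @param planted_fold_changes planted group-A/group-B mean ratios: a
#'   two-column data.frame (`metabolite` index or id, `ratio` > 0), a list of
#'   `c(index, ratio)` pairs, or NULL for none.
#' @param seed integer random seed; identical configurations reproduce
#'   identical studies bit for bit.
#' @return an object of class `study_config`.
#' @seealso [generate_study()]
#' @export
study_config <- function(n_metabolites = 280L,
                         n_per_group = c(A = 6L, B = 6L),
                         n_signatures = 4L,
                         group_signature_map = NULL,
                         dominance = 0.7,
                         signature_sparsity = 0.25,
                         noise_cv = 0.1,
                         sample_scale_cv = 0.1,
                         loading_scale = 100,
                         planted_fold_changes = data.frame(
                           metabolite = 1:3, ratio = c(4.31, 3.26, 3.16)),
                         seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) msig_stop(sprintf("invalid `%s`: %s", field, msg), "config_error")
  }
  chk(is_count(n_metabolites), "n_metabolites", "must be a count >= 1")
  chk(is.numeric(n_per_group) && length(n_per_group) >= 1 &&
        all(vapply(n_per_group, is_count, logical(1))),
      "n_per_group", "must be counts >= 1")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- LETTERS[seq_along(n_per_group)]
  chk(!anyDuplicated(names(n_per_group)), "n_per_group", "group labels must be unique")
  chk(is_count(n_signatures), "n_signatures", "must be a count >= 1")
  n_groups <- length(n_per_group)
  if (is.null(group_signature_map)) {
    idx <- if (n_signatures >= 2L * n_groups) 2L * seq_len(n_groups)
           else seq.int(n_signatures - min(n_groups, n_signatures) + 1L, n_signatures)
    idx <- rep_len(idx, n_groups)
    group_signature_map <- stats::setNames(idx, names(n_per_group))
  }
  chk(is.numeric(group_signature_map) &&
        setequal(names(group_signature_map), names(n_per_group)),
      "group_signature_map", "must map every group label to a signature index")
  group_signature_map <- group_signature_map[names(n_per_group)]
  chk(all(group_signature_map >= 1 & group_signature_map <= n_signatures),
      "group_signature_map", "signature indices out of range")
  chk(is.numeric(dominance) && length(dominance) == 1 &&
        dominance > 0.5 && dominance <= 1,
      "dominance", "must lie in (0.5, 1]")
  chk(is.numeric(signature_sparsity) && length(signature_sparsity) == 1 &&
        signature_sparsity > 0 && signature_sparsity <= 1,
      "signature_sparsity", "must lie in (0, 1]")
  chk(is.numeric(noise_cv) && length(noise_cv) == 1 && noise_cv >= 0,
      "noise_cv", "must be >= 0")
  chk(is.numeric(sample_scale_cv) && length(sample_scale_cv) == 1 && sample_scale_cv >= 0,
      "sample_scale_cv", "must be >= 0")
  chk(is.numeric(loading_scale) && length(loading_scale) == 1 && loading_scale > 0,
      "loading_scale", "must be > 0")
  fc <- normalize_fold_changes(planted_fold_changes, n_metabolites)
  chk(is_count(abs(seed) + 1), "seed", "must be a single integer")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_per_group = stats::setNames(as.integer(n_per_group), names(n_per_group)),
                 n_signatures = as.integer(n_signatures),
                 group_signature_map = stats::setNames(as.integer(group_signature_map),
                                                       names(group_signature_map)),
                 dominance = dominance,
                 signature_sparsity = signature_sparsity,
                 noise_cv = noise_cv,
                 sample_scale_cv = sample_scale_cv,
                 loading_scale = loading_scale,
                 planted_fold_changes = fc,
                 seed = as.integer(seed)),
            class = "study_config")
}

normalize_fold_changes <- function(x, n_metabolites) {
  if (is.null(x) || (is.list(x) && !is.data.frame(x) && length(x) == 0))
    return(data.frame(metabolite = integer(0), ratio = numeric(0)))
  if (is.list(x) && !is.data.frame(x))
    x <- data.frame(metabolite = vapply(x, `[`, numeric(1), 1),
                    ratio = vapply(x, `[`, numeric(1), 2))
  if (!is.data.frame(x) || !all(c("metabolite", "ratio") %in% names(x)))
    msig_stop("invalid `planted_fold_changes`: need columns `metabolite` and `ratio`",
              "config_error")
  idx <- x$metabolite
  if (!is.numeric(idx))
    msig_stop("invalid `planted_fold_changes`: metabolite must be a row index",
              "config_error")
  if (any(idx < 1 | idx > n_metabolites | idx != round(idx)))
    msig_stop("invalid `planted_fold_changes`: metabolite index out of range",
              "config_error")
  if (anyDuplicated(idx))
    msig_stop("invalid `planted_fold_changes`: duplicated metabolite index",
              "config_error")
  if (!all(is.finite(x$ratio)) || any(x$ratio <= 0))
    msig_stop("invalid `planted_fold_changes`: ratios must be > 0", "config_error")
  data.frame(metabolite = as.integer(idx), ratio = as.numeric(x$ratio))
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config: %d metabolites, %s samples, %d signatures, seed %d\n",
              x$n_metabolites,
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = "+"),
              x$n_signatures, x$seed))
  cat(sprintf("  dominance %.2f, sparsity %.2f, noise CV %.2f, %d planted fold change(s)\n",
              x$dominance, x$signature_sparsity, x$noise_cv,
              nrow(x$planted_fold_changes)))
  invisible(x)
}

#' Generate a synthetic metabolomics study
#'
#' Simulates a nonnegative metabolite-abundance matrix from planted factors:
#' `X = W H`, with `W` a metabolites x signatures profile matrix whose
#' columns sum to 1, `H` a signatures x samples loading matrix in which each
#' sample's group-dominant signature carries the configured `dominance`
#' fraction of its total loading.  Planted fold-change multipliers are then
#' applied to the group-A entries of the chosen metabolite rows, and finally
#' multiplicative log-normal noise (median 1, configured CV) is applied
#' entrywise.
#'
#' Metabolites carrying planted fold changes are given signature-neutral
#' baseline weights (the same weight in every signature), so their expected
#' group-mean ratio equals the planted ratio exactly, independent of the
#' signature mixing.
#'
#' @param config a [study_config()].
#' @return a list with components
#'   \describe{
#'     \item{matrix}{the simulated [metabolite_matrix()] with group labels;}
#'     \item{truth}{a `study_truth` object holding `true_signatures` (columns
#'       sum to 1), `true_loadings`, `group_labels`, `dominant_map`,
#'       `planted_fold_changes` and the seed.}
#'   }
#' @examples
#' st <- generate_study(study_config(seed = 7))
#' dim(st$matrix)
#' @export
generate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config"))
    msig_stop("`config` must be a study_config", "config_error")
  with_seed(config$seed, {
    k <- config$n_signatures
    m <- config$n_metabolites
    npg <- config$n_per_group
    n <- sum(npg)
    if (k > n)
      msig_stop("invalid `n_signatures`: more signatures than samples", "config_error")
    groups <- rep(names(npg), npg)
    met_ids <- sprintf("met%0*d", max(3L, nchar(m)), seq_len(m))
    sample_ids <- unlist(lapply(names(npg),
                                function(g) paste0(g, seq_len(npg[[g]]))),
                         use.names = FALSE)
    fc <- config$planted_fold_changes
    planted_idx <- fc$metabolite

    # signature profiles: sparse nonnegative columns summing to 1 exactly
    W <- matrix(0, m, k, dimnames = list(met_ids, paste0("P", seq_len(k))))
    rho <- numeric(0)
    if (length(planted_idx)) {
      rho <- stats::runif(length(planted_idx), 0.5, 1.5) / m
      if (sum(rho) > 0.5) rho <- rho * 0.5 / sum(rho)  # keep planted mass minor
    }
    free_idx <- setdiff(seq_len(m), planted_idx)
    if (length(free_idx) == 0)
      msig_stop("invalid `planted_fold_changes`: no unplanted metabolites left",
                "config_error")
    n_support <- max(1L, ceiling(config$signature_sparsity * length(free_idx)))
    for (d in seq_len(k)) {
      raw <- stats::rgamma(length(free_idx), shape = 1) * 1e-4
      support <- sample.int(length(free_idx), n_support)
      raw[support] <- stats::rgamma(n_support, shape = 1)
      W[free_idx, d] <- raw / sum(raw) * (1 - sum(rho))
      W[planted_idx, d] <- rho
    }

    # loadings: dominant share fixed at `dominance`, remainder Dirichlet-split
    dom <- config$group_signature_map[groups]
    H <- matrix(0, k, n, dimnames = list(colnames(W), sample_ids))
    sdlog_s <- sqrt(log(1 + config$sample_scale_cv^2))
    for (j in seq_len(n)) {
      total <- config$loading_scale *
        (if (sdlog_s > 0) stats::rlnorm(1, 0, sdlog_s) else 1)
      if (k == 1L) {
        H[1L, j] <- total
      } else {
        rest <- stats::rgamma(k - 1L, shape = 1)
        rest <- rest / sum(rest)
        share <- numeric(k)
        share[dom[j]] <- config$dominance
        share[-dom[j]] <- (1 - config$dominance) * rest
        H[, j] <- total * share
      }
    }

    X <- W %*% H
    if (length(planted_idx)) {
      in_a <- groups == names(npg)[1]
      X[planted_idx, in_a] <- X[planted_idx, in_a] * fc$ratio
    }
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      X <- X * matrix(stats::rlnorm(m * n, 0, sdlog), m, n)
    }

    labels <- stats::setNames(groups, sample_ids)
    truth <- structure(list(
      true_signatures = W,
      true_loadings = H,
      group_labels = labels,
      dominant_map = config$group_signature_map,
      planted_fold_changes = cbind(
        data.frame(metabolite = met_ids[planted_idx]),
        fc["ratio"]),
      seed = config$seed,
      config = config), class = "study_truth")
    list(matrix = metabolite_matrix(X, groups = labels), truth = truth)
  })
}

#' @export
print.study_truth <- function(x, ...) {
  cat(sprintf("study_truth: %d metabolites, %d samples, %d planted signatures (seed %d)\n",
              nrow(x$true_signatures), ncol(x$true_loadings),
              ncol(x$true_signatures), x$seed))
  invisible(x)
}

#' Generate a pathway library matched to a synthetic study
#'
#' Builds a named collection of metabolite sets over the study's metabolite
#' universe.  Pathways listed in `planted` draw at least 90% of their members
#' from the top-weighted metabolites of their paired planted signature, so
#' overrepresentation analysis of that signature's top metabolites has a
#' known positive; all other pathways draw members uniformly at random.
#'
#' @param n_pathways number of pathways.
#' @param size_range length-2 integer vector `c(min, max)` of pathway sizes;
#'   both within `[1, n_metabolites]`.
#' @param truth a `study_truth` from [generate_study()].
#' @param planted enrichment pairs: a list of `c(pathway_index,
#'   signature_index)` pairs (or a two-column data.frame).
#' @param seed integer random seed.
#' @return a [pathway_library()].
#' @export
generate_pathway_library <- function(n_pathways, size_range, truth,
                                     planted = list(), seed = 1L) {
  if (!inherits(truth, "study_truth"))
    msig_stop("`truth` must be a study_truth", "argument_error")
  universe <- rownames(truth$true_signatures)
  m <- length(universe)
  if (!is_count(n_pathways))
    msig_stop("invalid `n_pathways`: must be a count >= 1", "config_error")
  if (length(size_range) != 2 || !all(vapply(size_range, is_count, logical(1))) ||
      size_range[1] > size_range[2] || size_range[2] > m)
    msig_stop(sprintf("invalid `size_range`: need 1 <= min <= max <= %d", m),
              "config_error")
  if (is.data.frame(planted)) planted <- lapply(seq_len(nrow(planted)),
                                                function(i) as.numeric(planted[i, 1:2]))
  pl_path <- vapply(planted, `[`, numeric(1), 1)
  pl_sig <- vapply(planted, `[`, numeric(1), 2)
  if (length(pl_path) && (any(pl_path < 1 | pl_path > n_pathways) ||
                          any(pl_sig < 1 | pl_sig > ncol(truth$true_signatures))))
    msig_stop("invalid `planted`: pathway or signature index out of range",
              "config_error")
  with_seed(seed, {
    sizes <- resample(seq.int(size_range[1], size_range[2]), n_pathways,
                      replace = TRUE)
    paths <- vector("list", n_pathways)
    for (p in seq_len(n_pathways)) {
      size <- sizes[p]
      hit <- match(p, pl_path)
      if (!is.na(hit)) {
        w <- truth$true_signatures[, pl_sig[hit]]
        ranked <- universe[order(-w, universe)]
        n_top <- ceiling(0.9 * size)
        pool <- ranked[seq_len(min(m, n_top + ceiling(0.25 * size)))]
        members <- resample(pool, n_top)
        if (size > n_top)
          members <- c(members, resample(setdiff(universe, members), size - n_top))
      } else {
        members <- resample(universe, size)
      }
      paths[[p]] <- sort(members)
    }
    names(paths) <- sprintf("PW%0*d", max(2L, nchar(n_pathways)), seq_len(n_pathways))
    pathway_library(paths, universe = universe)
  })
}

#' Serialize the planted ground truth of a synthetic study
#'
#' Writes the true factor matrices as TSV tables and the scalar ground truth
#' (group labels, dominant-signature map, planted fold changes, seed) as JSON.
#'
#' @param truth a `study_truth`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_study_truth <- function(truth, dir) {
  if (!inherits(truth, "study_truth"))
    msig_stop("`truth` must be a study_truth", "argument_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, "true_signatures.tsv")
  load_path <- file.path(dir, "true_loadings.tsv")
  json_path <- file.path(dir, "truth.json")
  write_named_table(truth$true_signatures, "metabolite", sig_path)
  write_named_table(truth$true_loadings, "signature", load_path)
  jsonlite::write_json(list(
    group_labels = as.list(truth$group_labels),
    dominant_map = as.list(truth$dominant_map),
    planted_fold_changes = truth$planted_fold_changes,
    seed = truth$seed), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(sig_path, load_path, json_path))
}

# shared TSV writer for numeric matrices with an id column
write_named_table <- function(mat, id_name, path) {
  out <- data.frame(rownames(mat),
                    apply(mat, 2, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c(id_name, colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
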
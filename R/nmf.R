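#' Signature profile matrix
#'
#' Nonnegative metabolites x signatures weight matrix in which every column
#' sums to 1, so a signature is a relative-weight profile over metabolites.
#'
#' @param weights nonnegative numeric matrix, metabolites x signatures.
#' @param metabolite_ids row identifiers (default: rownames).
#' @param signature_names column identifiers (default: colnames, else
#'   `P1..Pk`).
#' @return an object of class `signature_set`.
#' @export
signature_set <- function(weights, metabolite_ids = rownames(weights),
                          signature_names = colnames(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights))
    msig_stop("`weights` must be a numeric matrix", "validation_error")
  if (is.null(signature_names)) signature_names <- paste0("P", seq_len(ncol(weights)))
  if (is.null(metabolite_ids))
    metabolite_ids <- sprintf("met%0*d", nchar(nrow(weights)), seq_len(nrow(weights)))
  if (any(!is.finite(weights)) || any(weights < 0))
    msig_stop("signature weights must be finite and >= 0", "validation_error")
  cs <- colSums(weights)
  if (any(abs(cs - 1) > 1e-9))
    msig_stop(sprintf("signature column(s) not summing to 1: %s",
                      paste(signature_names[abs(cs - 1) > 1e-9], collapse = ", ")),
              "validation_error")
  dimnames(weights) <- list(metabolite_ids, signature_names)
  structure(weights, class = c("signature_set", "matrix", "array"))
}

#' Sample loading matrix
#'
#' Nonnegative signatures x samples matrix of per-sample signature loadings
#' on the abundance scale (the scale removed from the signatures during
#' normalization lives here).
#'
#' @param loadings nonnegative numeric matrix, signatures x samples.
#' @param signature_names row identifiers.
#' @param sample_ids column identifiers.
#' @return an object of class `sample_weights`.
#' @export
sample_weights <- function(loadings, signature_names = rownames(loadings),
                           sample_ids = colnames(loadings)) {
  if (!is.matrix(loadings) || !is.numeric(loadings))
    msig_stop("`loadings` must be a numeric matrix", "validation_error")
  if (any(!is.finite(loadings)) || any(loadings < 0))
    msig_stop("loadings must be finite and >= 0", "validation_error")
  if (is.null(signature_names)) signature_names <- paste0("P", seq_len(nrow(loadings)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(loadings)))
  dimnames(loadings) <- list(signature_names, sample_ids)
  structure(loadings, class = c("sample_weights", "matrix", "array"))
}

#' Factorize a metabolite matrix by multiplicative-update NMF
#'
#' Approximates a nonnegative matrix `X` (metabolites x samples) as the
#' product `W H` of two nonnegative factors of inner dimension `k`, using
#' the classical multiplicative update rules for either the Frobenius
#' (squared-error) or the generalized Kullback-Leibler objective.  Both
#' factors are initialized with strictly positive uniform draws scaled to
#' the magnitude of `X`; a small epsilon is added to update denominators
#' only, never to the data.  After convergence the signature columns are
#' ordered by descending total loading and rescaled to sum to 1, with the
#' removed scale moved into the loadings, so `W H` is unchanged.
#'
#' @param X a [metabolite_matrix()] or nonnegative numeric matrix.
#' @param k factorization rank, `1 <= k <= min(dim(X))`.
#' @param objective `"frobenius"` (default) or `"kl"`.
#' @param seed integer seed for the random initialization; results are
#'   reproducible under `(X, k, objective, seed)`.
#' @param max_iter maximum number of update sweeps.
#' @param rel_tol relative objective-decrease convergence threshold, checked
#'   every 10 sweeps.
#' @param n_starts number of independently initialized runs (seeds `seed`,
#'   `seed + 1`, ...); the run with the lowest final objective is returned.
#'   Multiplicative updates can stall in local minima, so a handful of
#'   restarts is cheap insurance when a single best fit is wanted; keep the
#'   default 1 when run-to-run variability is itself of interest (as in
#'   consensus stability analysis).
#' @param eps epsilon added to update denominators.
#' @return an object of class `nmf_fit` with components `signatures`
#'   ([signature_set()]), `loadings` ([sample_weights()]),
#'   `objective_trace` (per-sweep objective values, non-increasing),
#'   `n_iter`, `converged`, `seed` and `objective_kind`.
#' @examples
#' X <- outer(c(1, 2), c(3, 1, 2))
#' fit <- nmf_factorize(X, k = 1, seed = 1)
#' reconstruction_error(X, fit)
#' @export
nmf_factorize <- function(X, k, objective = c("frobenius", "kl"), seed = 1L,
                          max_iter = 2000L, rel_tol = 1e-6, n_starts = 1L,
                          eps = 1e-12) {
  X <- as_metabolite_matrix(X)
  objective <- match.arg(objective)
  m <- nrow(X); n <- ncol(X)
  if (!is_count(k) || k > min(m, n))
    msig_stop(sprintf("`k` must be an integer in [1, %d]", min(m, n)),
              "argument_error")
  if (!is_count(max_iter)) msig_stop("`max_iter` must be >= 1", "argument_error")
  if (!is.numeric(rel_tol) || rel_tol <= 0)
    msig_stop("`rel_tol` must be > 0", "argument_error")
  if (!is_count(n_starts)) msig_stop("`n_starts` must be >= 1", "argument_error")
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts) - 1L, function(off)
      nmf_factorize(X, k, objective = objective, seed = as.integer(seed) + off,
                    max_iter = max_iter, rel_tol = rel_tol, n_starts = 1L,
                    eps = eps))
    finals <- vapply(fits, function(f) f$objective_trace[f$n_iter], numeric(1))
    return(fits[[which.min(finals)]])
  }
  k <- as.integer(k)
  V <- unclass(X)
  attr(V, "groups") <- NULL

  with_seed(seed, {
    scale0 <- sqrt(max(mean(V), .Machine$double.xmin) / k)
    W <- matrix(stats::runif(m * k, min = .Machine$double.eps, max = 1),
                m, k) * scale0
    H <- matrix(stats::runif(k * n, min = .Machine$double.eps, max = 1),
                k, n) * scale0
    trace <- numeric(max_iter)
    converged <- FALSE
    prev_obj <- NA_real_
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      if (objective == "frobenius") {
        H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
        W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
        R <- V - W %*% H
        obj <- 0.5 * sum(R * R)
      } else {
        WH <- W %*% H
        H <- H * crossprod(W, V / (WH + eps)) / (colSums(W) + eps)
        WH <- W %*% H
        W <- W * ((V / (WH + eps)) %*% t(H)) /
          rep(rowSums(H) + eps, each = m)
        WH <- W %*% H
        obj <- sum(ifelse(V > 0, V * log(V / (WH + eps)), 0) - V + WH)
      }
      trace[it] <- obj
      if (it %% 10L == 0L) {
        if (!is.na(prev_obj) &&
            (prev_obj - obj) <= rel_tol * max(abs(prev_obj), eps)) {
          converged <- TRUE
          break
        }
        prev_obj <- obj
      }
    }
    ord <- order(rowSums(H), decreasing = TRUE)
    W <- W[, ord, drop = FALSE]
    H <- H[ord, , drop = FALSE]
    norm <- normalize_signatures(W, H,
                                 metabolite_ids = rownames(X),
                                 sample_ids = colnames(X))
    structure(list(signatures = norm$signatures,
                   loadings = norm$loadings,
                   objective_trace = trace[seq_len(it)],
                   n_iter = it,
                   converged = converged,
                   seed = as.integer(seed),
                   objective_kind = objective),
              class = "nmf_fit")
  })
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: %d metabolites x %d signatures x %d samples (%s)\n",
              nrow(x$signatures), ncol(x$signatures), ncol(x$loadings),
              x$objective_kind))
  cat(sprintf("  %d sweeps, %sconverged, final objective %.6g\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$objective_trace[x$n_iter]))
  invisible(x)
}

#' Normalize raw NMF factors to the unit-column-sum convention
#'
#' Rescales every signature column of `W` to sum to 1 and moves the removed
#' scale into the corresponding loading row of `H`, so the product `W H` is
#' preserved exactly.
#'
#' @param W nonnegative raw signature matrix (metabolites x k).
#' @param H nonnegative raw loading matrix (k x samples).
#' @param metabolite_ids,sample_ids optional identifiers for the outputs.
#' @return a list with elements `signatures` ([signature_set()]) and
#'   `loadings` ([sample_weights()]).
#' @export
normalize_signatures <- function(W, H, metabolite_ids = rownames(W),
                                 sample_ids = colnames(H)) {
  if (!is.matrix(W)) W <- as.matrix(W)
  if (!is.matrix(H)) H <- as.matrix(H)
  if (ncol(W) != nrow(H))
    msig_stop("`W` and `H` have mismatched inner dimension", "argument_error")
  if (any(W < 0) || any(H < 0))
    msig_stop("factors must be nonnegative", "validation_error")
  s <- colSums(W)
  if (any(s == 0))
    msig_stop(sprintf("degenerate signature column(s) summing to 0: %s",
                      paste(which(s == 0), collapse = ", ")),
              "degenerate_signature")
  sig_names <- colnames(W)
  if (is.null(sig_names)) sig_names <- paste0("P", seq_len(ncol(W)))
  Wn <- matrix(sweep(W, 2, s, "/"), nrow(W), ncol(W))
  Hn <- matrix(H * s, nrow(H), ncol(H))
  list(signatures = signature_set(Wn, metabolite_ids = metabolite_ids,
                                  signature_names = sig_names),
       loadings = sample_weights(Hn, signature_names = sig_names,
                                 sample_ids = sample_ids))
}

#' Reconstruction error of a factorization
#'
#' @param X the matrix that was factorized.
#' @param fit an `nmf_fit` (or a list with `signatures` and `loadings`).
#' @param kind `"frobenius_rel"` (Frobenius norm of the residual divided by
#'   the Frobenius norm of `X`) or `"kl"` (generalized Kullback-Leibler
#'   divergence).
#' @return a single nonnegative number; 0 iff the product equals `X`.
#' @export
reconstruction_error <- function(X, fit, kind = c("frobenius_rel", "kl")) {
  kind <- match.arg(kind)
  X <- as_metabolite_matrix(X)
  W <- unclass(fit$signatures); H <- unclass(fit$loadings)
  if (nrow(W) != nrow(X) || ncol(H) != ncol(X) || ncol(W) != nrow(H))
    msig_stop("factor dimensions do not match `X`", "argument_error")
  P <- W %*% H
  V <- unclass(X)
  if (kind == "frobenius_rel") {
    sqrt(sum((V - P)^2) / sum(V^2))
  } else {
    sum(ifelse(V > 0, V * log(V / pmax(P, .Machine$double.xmin)), 0) - V + P)
  }
}
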
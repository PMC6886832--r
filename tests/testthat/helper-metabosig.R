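# shared fixtures and independent oracles used across test files

# small, well-separated two-group study for fast tests
small_study <- function(seed = 1, noise_cv = 0.05, n_metabolites = 80,
                        n_signatures = 2, n_per_group = c(A = 6, B = 6),
                        group_signature_map = NULL, ...) {
  generate_study(study_config(
    n_metabolites = n_metabolites, n_per_group = n_per_group,
    n_signatures = n_signatures, group_signature_map = group_signature_map,
    noise_cv = noise_cv, planted_fold_changes = NULL, seed = seed, ...))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# sample() without the scalar-x surprise
resample_test <- function(x, size) x[sample.int(length(x), size)]

# greedy maximum-similarity matching of recovered to planted signature columns
matched_cosines <- function(W, W_true) {
  k <- ncol(W)
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cosine(W[, i], W_true[, j])))
  out <- numeric(k)
  for (r in seq_len(k)) {
    ij <- which(S == max(S), arr.ind = TRUE)[1, ]
    out[r] <- S[ij[1], ij[2]]
    S[ij[1], ] <- -2; S[, ij[2]] <- -2
  }
  out
}

# brute-force average-linkage cophenetic distances (UPGMA: inter-cluster
# distance = mean over all original cross-cluster pairs), independent of
# stats::hclust / stats::cophenetic
oracle_avg_link_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  CD <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) CD[a, b] <- CD[b, a] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  CD
}

# exhaustive hypergeometric upper-tail probability by enumerating every
# possible hit draw from a small universe
oracle_ora_enumerate <- function(n_universe, n_pathway, n_hits, observed) {
  draws <- utils::combn(n_universe, n_hits)
  in_pathway <- draws <= n_pathway  # wlog pathway = first n_pathway elements
  mean(colSums(in_pathway) >= observed)
}
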
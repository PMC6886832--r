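test_that("dominant signature is the per-sample argmax with low-index tie breaking", {
  L <- matrix(c(0.1, 0.7, 0.2,
                0.5, 0.5, 0.0), nrow = 3,
              dimnames = list(paste0("P", 1:3), c("s1", "s2")))
  dom <- dominant_signature(L)
  expect_identical(dom$signature_index, c(2L, 1L))
  expect_identical(dom$tie, c(FALSE, TRUE))

  L0 <- L; L0[, 2] <- 0
  expect_error(dominant_signature(L0), "s2", class = "undefined_dominance")
})

test_that("true loadings make each group's planted signature dominant", {
  st <- generate_study(study_config(seed = 4))
  dom <- dominant_signature(st$truth$true_loadings)
  expect_identical(dom$signature_index,
                   unname(st$truth$dominant_map[st$truth$group_labels]))
  expect_false(any(dom$tie))
})

test_that("fitted loadings give one consistent dominant signature per group", {
  st <- generate_study(study_config(seed = 1))
  fit <- nmf_factorize(st$matrix, 4, seed = 1, n_starts = 5)
  dom <- dominant_signature(fit$loadings)
  g <- attr(st$matrix, "groups")
  per_group <- split(dom$signature_index, g)
  expect_length(unique(per_group$A), 1L)
  expect_length(unique(per_group$B), 1L)
  expect_false(unique(per_group$A) == unique(per_group$B))
})

test_that("two samples merge once and are split at cut_k = 2", {
  L <- matrix(c(1, 3, 4, 1), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  cl <- cluster_samples(L, cut_k = 2)
  expect_identical(nrow(cl$hclust$merge), 1L)
  expect_identical(unname(cl$flat_labels), c(1L, 2L))
})

test_that("default synthetic study clusters cleanly by group at cut_k = 2", {
  st <- generate_study(study_config(seed = 1))
  fit <- nmf_factorize(st$matrix, 4, seed = 1, n_starts = 5)
  cl <- cluster_samples(fit$loadings, cut_k = 2, groups = attr(st$matrix, "groups"))
  expect_identical(unname(cl$purity_by_group["A"]), 1)
  expect_identical(unname(cl$purity_by_group["B"]), 1)
  # all six group-A samples share one cluster
  labs <- cl$flat_labels[attr(st$matrix, "groups") == "A"]
  expect_length(unique(labs), 1L)
})

test_that("identical profiles merge at height zero and rescaling a sample changes nothing", {
  L <- matrix(rep(c(2, 1, 3), 4), nrow = 3,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
  cl <- cluster_samples(L, distance = "euclidean", cut_k = 1)
  expect_true(all(abs(cl$hclust$height) <= 1e-12))

  st <- small_study(seed = 7, n_signatures = 3)
  fit <- nmf_factorize(st$matrix, 3, seed = 2)
  L1 <- unclass(fit$loadings)
  L2 <- L1; L2[, 3] <- 7 * L2[, 3]
  c1 <- cluster_samples(L1, cut_k = 2)
  c2 <- cluster_samples(L2, cut_k = 2)
  expect_identical(c1$flat_labels, c2$flat_labels)
  expect_equal(c1$hclust$height, c2$hclust$height, tolerance = 1e-12)
})

test_that("a constant profile is rejected under correlation distance", {
  L <- matrix(c(1, 2, 3, 2, 2, 2), 3, 2,
              dimnames = list(paste0("P", 1:3), c("s1", "s2")))
  expect_error(cluster_samples(L, distance = "correlation"), "s2",
               class = "degenerate_profile")
  # but euclidean handles it
  expect_s3_class(cluster_samples(L, distance = "euclidean"),
                  "cluster_assignment")
})

test_that("merge heights are non-decreasing for average linkage", {
  st <- small_study(seed = 8, n_signatures = 3, noise_cv = 0.2)
  fit <- nmf_factorize(st$matrix, 3, seed = 1)
  cl <- cluster_samples(fit$loadings)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("top_metabolites honours both truncation rules and deterministic tie order", {
  W <- matrix(c(0.5, 0.3, 0.1, 0.1), 4, 1,
              dimnames = list(c("m1", "m2", "m3", "m4"), "P1"))
  sig <- signature_set(W)
  expect_identical(top_metabolites(sig, "P1", "cumulative_mass", 0.7)$metabolite,
                   c("m1", "m2"))
  expect_identical(top_metabolites(sig, "P1", "weight_floor", 0)$metabolite,
                   c("m1", "m2", "m3", "m4"))
  # ties broken by metabolite identifier
  W2 <- matrix(c(0.25, 0.25, 0.4, 0.1), 4, 1,
               dimnames = list(c("mB", "mA", "mC", "mD"), "P1"))
  expect_identical(top_metabolites(signature_set(W2), 1,
                                   "cumulative_mass", 0.9)$metabolite,
                   c("mC", "mA", "mB"))
  expect_error(top_metabolites(sig, "P9"), class = "lookup_error")
})

test_that("top metabolites at 90% mass stay inside the planted support and cover its mass", {
  st <- small_study(seed = 9, n_metabolites = 200, n_signatures = 3,
                    signature_sparsity = 0.2)
  truth_sig <- signature_set(st$truth$true_signatures)
  for (d in 1:3) {
    tab <- top_metabolites(truth_sig, d, "cumulative_mass", 0.9)
    # support metabolites carry ~1/40 weight each, background ~1e-5
    support <- rownames(st$truth$true_signatures)[
      st$truth$true_signatures[, d] > 1e-4]
    # precision: no background metabolite sneaks into the 90%-mass prefix
    expect_true(all(tab$metabolite %in% support))
    # coverage: the prefix captures at least 90% of the signature's weight
    expect_gte(sum(tab$weight), 0.9)
  }
})

test_that("dendrograms export as parseable Newick with sample tips", {
  st <- small_study(seed = 10, n_metabolites = 30)
  fit <- nmf_factorize(st$matrix, 2, seed = 1)
  cl <- cluster_samples(fit$loadings)
  nwk <- as_newick(cl)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, colnames(st$matrix))
})
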
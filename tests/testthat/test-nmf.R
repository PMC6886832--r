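test_that("an exact rank-1 nonnegative matrix is recovered to near machine precision", {
  X <- outer(c(1, 2), c(3, 1, 2))
  fit <- nmf_factorize(X, 1, seed = 1, max_iter = 5000, rel_tol = 1e-12)
  expect_lte(reconstruction_error(X, fit), 1e-6)
})

test_that("an all-zero metabolite row yields a zero signature weight row", {
  set.seed(1)
  X <- matrix(runif(10 * 6, 1, 5), 10, 6)
  X[4, ] <- 0
  fit <- nmf_factorize(X, 2, seed = 3)
  expect_true(all(unclass(fit$signatures)[4, ] <= 1e-12))
})

test_that("the objective trace is non-increasing and factors stay nonnegative", {
  set.seed(7)
  X <- matrix(runif(20 * 8, 0, 10), 20, 8)
  for (obj in c("frobenius", "kl")) {
    for (k in c(2, 3)) {
      fit <- nmf_factorize(X, k, objective = obj, seed = k)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) <= 1e-10 * (1 + abs(tr[1]))),
                  label = sprintf("monotone trace (%s, k=%d)", obj, k))
      expect_true(all(unclass(fit$signatures) >= 0))
      expect_true(all(unclass(fit$loadings) >= 0))
      expect_true(all(abs(colSums(fit$signatures) - 1) <= 1e-9))
    }
  }
})

test_that("factorization is reproducible under (X, k, objective, seed)", {
  set.seed(2)
  X <- matrix(runif(15 * 6, 0, 4), 15, 6)
  a <- nmf_factorize(X, 2, seed = 5)
  b <- nmf_factorize(X, 2, seed = 5)
  expect_identical(unclass(a$signatures), unclass(b$signatures))
  expect_identical(unclass(a$loadings), unclass(b$loadings))
})

test_that("rescaling the data leaves normalized signatures unchanged and scales loadings", {
  set.seed(3)
  X <- matrix(runif(25 * 8, 0, 5), 25, 8)
  f1 <- nmf_factorize(X, 3, seed = 2, rel_tol = 1e-10, max_iter = 4000)
  f2 <- nmf_factorize(3.7 * X, 3, seed = 2, rel_tol = 1e-10, max_iter = 4000)
  expect_equal(unclass(f1$signatures), unclass(f2$signatures), tolerance = 1e-6)
  expect_equal(3.7 * unclass(f1$loadings), unclass(f2$loadings), tolerance = 1e-6)
})

test_that("planted signatures are recovered on noiseless well-separated data", {
  cfg <- study_config(n_metabolites = 120, n_per_group = c(A = 8, B = 8),
                      n_signatures = 3, group_signature_map = c(A = 2, B = 3),
                      signature_sparsity = 0.15, noise_cv = 0,
                      planted_fold_changes = NULL, seed = 4)
  st <- generate_study(cfg)
  fit <- nmf_factorize(st$matrix, 3, seed = 1, n_starts = 5,
                       max_iter = 8000, rel_tol = 1e-10)
  sims <- matched_cosines(unclass(fit$signatures), st$truth$true_signatures)
  expect_true(all(sims >= 0.95))
})

test_that("signature normalization preserves the factor product and rejects zero columns", {
  W <- matrix(c(0.2, 0.3, 0.5), 3, 1)
  H <- matrix(c(1, 4), 1, 2)
  norm <- normalize_signatures(W, H)
  expect_equal(unclass(norm$signatures), W, ignore_attr = TRUE)
  expect_equal(unclass(norm$loadings), H, ignore_attr = TRUE)

  W2 <- matrix(c(2, 3, 5), 3, 1)
  norm2 <- normalize_signatures(W2, H)
  expect_equal(unclass(norm2$signatures)[, 1], c(0.2, 0.3, 0.5),
               ignore_attr = TRUE)
  expect_equal(unclass(norm2$loadings)[1, ], c(10, 40), ignore_attr = TRUE)
  expect_equal(unclass(norm2$signatures) %*% unclass(norm2$loadings), W2 %*% H,
               ignore_attr = TRUE)

  expect_error(normalize_signatures(matrix(0, 3, 1), H),
               class = "degenerate_signature")
})

test_that("reconstruction error matches an elementwise oracle and its edge cases", {
  # exact product
  W <- matrix(c(0.5, 0.5), 2, 1); H <- matrix(c(2, 6), 1, 2)
  fit <- list(signatures = W, loadings = H)
  expect_identical(reconstruction_error(W %*% H, fit), 0)
  # 1x1 case: |2 - 1| / |1|
  expect_identical(reconstruction_error(matrix(1, 1, 1),
                                        list(signatures = matrix(1, 1, 1),
                                             loadings = matrix(2, 1, 1))), 2 - 1)
  # random instance vs loop-coded Frobenius and KL
  set.seed(4)
  X <- matrix(runif(10 * 6, 0.5, 3), 10, 6)
  f <- nmf_factorize(X, 2, seed = 1)
  P <- unclass(f$signatures) %*% unclass(f$loadings)
  num <- 0; den <- 0; kl <- 0
  for (i in 1:10) for (j in 1:6) {
    num <- num + (X[i, j] - P[i, j])^2
    den <- den + X[i, j]^2
    kl <- kl + X[i, j] * log(X[i, j] / P[i, j]) - X[i, j] + P[i, j]
  }
  expect_equal(reconstruction_error(X, f, "frobenius_rel"), sqrt(num / den),
               tolerance = 1e-12)
  expect_equal(reconstruction_error(X, f, "kl"), kl, tolerance = 1e-12)
})

test_that("invalid factorization arguments are rejected", {
  X <- matrix(1:12 / 2, 4, 3)
  expect_error(nmf_factorize(X, 0), class = "argument_error")
  expect_error(nmf_factorize(X, 4), class = "argument_error")
  Xneg <- X; Xneg[2, 2] <- -1
  expect_error(nmf_factorize(Xneg, 2), class = "validation_error")
  expect_error(reconstruction_error(matrix(1, 3, 3),
                                    list(signatures = matrix(1, 2, 1),
                                         loadings = matrix(1, 1, 3))),
               class = "argument_error")
})
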
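make_mm <- function(values, groups) {
  rownames(values) <- sprintf("m%d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  metabolite_matrix(values, groups = groups)
}

test_that("identical groups give a zero t statistic and p = 1", {
  X <- make_mm(matrix(c(1, 2, 3, 1, 2, 3), 1, 6), rep(c("A", "B"), each = 3))
  expect_equal(unname(two_group_test(X)), 1, tolerance = 1e-15)
})

test_that("pooled t-test matches stats::t.test with equal variances", {
  set.seed(15)
  for (r in 1:10) {
    a <- runif(4, 0, 10); b <- runif(5, 0, 10)
    X <- make_mm(matrix(c(a, b), 1), rep(c("A", "B"), c(4, 5)))
    expect_equal(unname(two_group_test(X, test = "student_t")),
                 stats::t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(unname(two_group_test(X, test = "welch_t")),
                 stats::t.test(a, b)$p.value,
                 tolerance = 1e-10)
    expect_equal(unname(two_group_test(X, test = "mann_whitney")),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # closed-form hand check: {1,2,3} vs {4,5,6} with 4 degrees of freedom
  X <- make_mm(matrix(c(1, 2, 3, 4, 5, 6), 1), rep(c("A", "B"), each = 3))
  t_stat <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(unname(two_group_test(X)), 2 * stats::pt(-abs(t_stat), 4),
               tolerance = 1e-10)
})

test_that("zero within-group variance is handled without epsilon fudging", {
  X <- make_mm(matrix(c(1, 1, 1, 2, 2, 2), 1), rep(c("A", "B"), each = 3))
  expect_equal(unname(two_group_test(X)), 0)
  X2 <- make_mm(matrix(rep(3, 6), 1), rep(c("A", "B"), each = 3))
  expect_true(is.na(two_group_test(X2)))
})

test_that("planted three-fold changes are detected at n = 6 per group", {
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    cfg <- study_config(n_metabolites = 30,
                        planted_fold_changes = data.frame(metabolite = 1, ratio = 3),
                        noise_cv = 0.1, seed = 400 + r)
    st <- generate_study(cfg)
    p <- two_group_test(st$matrix)[1]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("fold changes follow the larger-over-smaller convention with direction flags", {
  X <- make_mm(matrix(c(rep(10, 4), rep(10, 4),
                        2, 2, 2, 2, 8, 8, 8, 8), 2, 8, byrow = TRUE),
               rep(c("A", "B"), each = 4))
  tab <- fold_change(X, reference = "A")
  expect_equal(tab$fold_change[1], 1)
  expect_identical(tab$direction[1], "unchanged")
  expect_equal(tab$fold_change[2], 4)
  expect_identical(tab$direction[2], "down")
  expect_true(all(tab$fold_change >= 1, na.rm = TRUE))
})

test_that("a zero group mean yields an undefined ratio, not a patched one", {
  X <- make_mm(matrix(c(0, 0, 0, 5, 6, 7), 1), rep(c("A", "B"), each = 3))
  tab <- fold_change(X)
  expect_true(tab$undefined_ratio[1])
  expect_true(is.na(tab$fold_change[1]))
})

test_that("swapping the reference flips direction but not fold change or p", {
  st <- generate_study(study_config(seed = 16))
  ta <- fold_change(st$matrix, reference = "A")
  tb <- fold_change(st$matrix, reference = "B")
  expect_equal(ta$fold_change, tb$fold_change, tolerance = 1e-12)
  expect_equal(ta$p_value, tb$p_value, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(flip[ta$direction]), tb$direction)
})

test_that("estimated fold change is consistent as the group size grows", {
  cfg <- study_config(n_per_group = c(A = 200, B = 200), noise_cv = 0.1,
                      planted_fold_changes = data.frame(metabolite = 1,
                                                        ratio = 4.31),
                      seed = 17)
  st <- generate_study(cfg)
  est <- fold_change(st$matrix)$fold_change[1]
  expect_lt(abs(est - 4.31) / 4.31, 0.02)
})

test_that("p-values are uniform under the global null", {
  # same dominant signature in both groups, no planted changes, no scale
  # variation: group distributions are identical so p should be U(0,1)
  rejections <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    cfg <- study_config(group_signature_map = c(A = 1, B = 1), dominance = 1,
                        sample_scale_cv = 0, noise_cv = 0.1,
                        planted_fold_changes = NULL, seed = 600 + r)
    st <- generate_study(cfg)
    p <- two_group_test(st$matrix)
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    if (ks$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, ceiling(0.05 * n_rep))
})

test_that("group preconditions are enforced", {
  X <- make_mm(matrix(1:8, 2, 4), c("A", "A", "B", "C"))
  expect_error(two_group_test(X), class = "argument_error")
  X2 <- make_mm(matrix(1:8, 2, 4), c("A", "A", "A", "B"))
  expect_error(two_group_test(X2), class = "argument_error")
  X3 <- make_mm(matrix(1:8, 2, 4), c("A", "A", "B", "B"))
  expect_error(fold_change(X3, reference = "Z"), class = "argument_error")
})
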
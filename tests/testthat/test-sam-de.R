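test_that("the moderated statistic follows d = diff / (s + s0)", {
  M <- expr_from_matrix(rbind(c(5, 5, 3, 3),    # equal within groups, s = 0
                              c(4, 4, 2, 2),
                              c(7, 7, 7, 7)),   # equal means: d = 0
                        probes = c("pa", "pb", "pc"),
                        arrays = c("A1", "A2", "B1", "B2"))
  res <- sam_statistic(M, c("A1", "A2"), c("B1", "B2"), s0 = 0.5)
  expect_equal(res$s, c(0, 0, 0))
  expect_equal(res$d, c(2 / 0.5, 2 / 0.5, 0))

  # zero numerator gives d = 0 for any positive s0
  expect_equal(sam_statistic(M, c("A1", "A2"), c("B1", "B2"), s0 = 7)$d[3], 0)

  # s0 -> large drives every statistic toward 0
  big <- sam_statistic(M, c("A1", "A2"), c("B1", "B2"), s0 = 1e9)
  expect_true(all(abs(big$d) < 1e-8))

  expect_error(sam_statistic(M, "A1", c("B1", "B2")), ">= 2 arrays")
})

test_that("pooled standard error matches the two-sample formula", {
  set.seed(88)
  M <- two_group_expr(n_probes = 20, n_per_group = 4, sd = 2)
  res <- sam_statistic(M, paste0("A", 1:4), paste0("B", 1:4), s0 = 0)
  X <- as.matrix(M[, -1])
  i <- 7
  a <- X[i, 1:4]; b <- X[i, 5:8]
  pooled <- sqrt((1 / 4 + 1 / 4) / 6 * (sum((a - mean(a))^2) + sum((b - mean(b))^2)))
  expect_equal(res$s[i], pooled)
  expect_equal(res$d[i], (mean(a) - mean(b)) / pooled)
})

test_that("s0 percentile search is deterministic and within the s range", {
  M <- two_group_expr(n_probes = 500, n_per_group = 3, sd = 1, seed = 4)
  s0a <- estimate_s0(M, paste0("A", 1:3), paste0("B", 1:3))
  s0b <- estimate_s0(M, paste0("A", 1:3), paste0("B", 1:3))
  expect_identical(s0a, s0b)
  s <- sam_statistic(M, paste0("A", 1:3), paste0("B", 1:3), 0)$s
  expect_gte(s0a, min(s)); expect_lte(s0a, max(s))

  # all standard errors equal: any percentile gives that value
  Mc <- expr_from_matrix(matrix(rep(c(1, 2, 3, 7, 8, 9), 5), 5, byrow = TRUE),
                         arrays = c("A1", "A2", "A3", "B1", "B2", "B3"))
  expect_equal(estimate_s0(Mc, paste0("A", 1:3), paste0("B", 1:3)),
               sam_statistic(Mc, paste0("A", 1:3), paste0("B", 1:3), 0)$s[1])

  # degenerate all-zero s: positive floor with a warning
  Mz <- expr_from_matrix(matrix(rep(c(4, 4, 2, 2), 3), 3, byrow = TRUE),
                         arrays = c("A1", "A2", "B1", "B2"))
  expect_warning(s0z <- estimate_s0(Mz, c("A1", "A2"), c("B1", "B2")), "zero")
  expect_gt(s0z, 0)
})

test_that("exhaustive permutation p-values match brute-force enumeration", {
  set.seed(19)
  M <- two_group_expr(n_probes = 12, n_per_group = 3, delta = 3, sd = 1, seed = 19)
  res <- permutation_pvalues(M, paste0("A", 1:3), paste0("B", 1:3), s0 = 0.1,
                             n_perm = 1000)
  expect_identical(attr(res, "mode"), "exhaustive")
  expect_identical(attr(res, "n_perm_used"), 20)

  # independent brute force: all 20 subsets of size 3 as "group A"
  X <- as.matrix(M[, -1])
  brute <- sapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    dstat <- function(ia) {
      a <- x[ia]; b <- x[-ia]
      s <- sqrt((1 / 3 + 1 / 3) / 4 * (sum((a - mean(a))^2) + sum((b - mean(b))^2)))
      (mean(a) - mean(b)) / (s + 0.1)
    }
    d_obs <- dstat(1:3)
    perms <- utils::combn(6, 3)
    mean(abs(apply(perms, 2, dstat)) >= abs(d_obs) - 1e-12)
  })
  expect_equal(res$p, brute)
  expect_true(all(res$p * 20 == round(res$p * 20)))  # multiples of 1/20
  expect_gte(min(res$p), 2 / 20)  # identity and group swap always count
})

test_that("sampled mode is seeded-reproducible and add-one biased", {
  M <- two_group_expr(n_probes = 30, n_per_group = 5, delta = 2, seed = 3)
  a <- permutation_pvalues(M, paste0("A", 1:5), paste0("B", 1:5), s0 = 0.1,
                           n_perm = 50, seed = 11)
  b <- permutation_pvalues(M, paste0("A", 1:5), paste0("B", 1:5), s0 = 0.1,
                           n_perm = 50, seed = 11)
  expect_identical(a$p, b$p)
  expect_identical(attr(a, "mode"), "sampled")
  expect_gte(min(a$p), 1 / 51)
  expect_error(permutation_pvalues(M, paste0("A", 1:5), paste0("B", 1:5),
                                   n_perm = 50), "seed")
})

test_that("exhaustive mode engages exactly when n_perm covers all assignments", {
  M <- two_group_expr(n_probes = 10, n_per_group = 3, seed = 6)
  ex <- permutation_pvalues(M, paste0("A", 1:3), paste0("B", 1:3), s0 = 0.1,
                            n_perm = 20)
  more <- permutation_pvalues(M, paste0("A", 1:3), paste0("B", 1:3), s0 = 0.1,
                              n_perm = 10000)
  expect_identical(ex$p, more$p)
  sampled <- permutation_pvalues(M, paste0("A", 1:3), paste0("B", 1:3),
                                 s0 = 0.1, n_perm = 19, seed = 2)
  expect_identical(attr(sampled, "mode"), "sampled")
})

test_that("BH q-values reproduce the step-up oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  q <- bh_fdr(p)
  expect_true(all(q >= p))             # q >= p always under BH
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p-rank
  expect_true(all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sam_test assembles the full result with metadata and tidiers", {
  M <- two_group_expr(n_probes = 40, n_per_group = 3, delta = 4, seed = 10)
  fit <- sam_test(M, paste0("A", 1:3), paste0("B", 1:3), n_perm = 100)
  tab <- tidy(fit)
  expect_named(tab, c("probe_id", "mean_diff", "s", "d", "p", "q"))
  expect_true(all(tab$q >= tab$p))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  g <- glance(fit)
  expect_equal(g$n_probes, 40)
  expect_equal(g$mode, "exhaustive")
  expect_s3_class(autoplot(fit), "ggplot")
})
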
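test_that("dome summary arithmetic: per-21-fields is exactly 21 x per-field", {
  # 10 flasks x 21 fields, 21 domes total -> 0.1 per field, 2.1 per 21 fields
  counts <- integer(210)
  counts[seq(1, 210, by = 10)] <- 1L
  domes <- tibble::tibble(flask = rep(1:10, each = 21),
                          field_index = rep(1:21, 10),
                          count = counts)
  s <- dome_summary(domes)
  expect_equal(s$domes_per_field, 0.1)
  expect_equal(s$domes_per_21_fields, 2.1)
  expect_true(s$dome_positive)

  zero <- dplyr::mutate(domes, count = 0L)
  s0 <- dome_summary(zero)
  expect_equal(s0$domes_per_field, 0)
  expect_equal(s0$domes_per_21_fields, 0)
  expect_false(s0$dome_positive)

  expect_error(dome_summary(domes[-1, ]), "expected 21")
  set.seed(8)
  for (i in 1:10) {
    d <- tibble::tibble(flask = rep(1:3, each = 21), field_index = rep(1:21, 3),
                        count = rpois(63, 2))
    s <- dome_summary(d)
    expect_equal(s$domes_per_21_fields, 21 * s$domes_per_field)
  }
})

test_that("dome summary recovers a simulated Poisson rate", {
  p <- simulate_phenotype(2.7, n_flasks = 300, seed = 15)
  s <- dome_summary(p$domes)
  expect_lt(abs(s$domes_per_field - 2.7), 3 * sqrt(2.7 / (21 * 300)) * 1.5)
})

test_that("TER summary subtracts the blank, scales by area and combines days", {
  ter <- tidyr::expand_grid(filter = 1:3, day = 5:7, reading_index = 1:8)
  ter$resistance_ohm <- 100 + 40  # constant readings: blank 100, signal 40
  ter$blank_ohm <- 100
  ter$area_cm2 <- 0.5
  s <- ter_summary(ter)
  expect_equal(s$daily$mean_ter, rep(20, 3))  # (140-100) * 0.5
  expect_equal(s$daily$sem_ter, rep(0, 3))
  expect_equal(s$combined$combined_ter, 20)

  expect_error(ter_summary(dplyr::filter(ter, day != 6)), "missing TER day")
})

test_that("combined TER reproduces the printed worked examples", {
  tab <- mcf7_ter_daily()
  combined <- vapply(seq_len(nrow(tab)), function(i) {
    ter_combine_days(c(tab$day5_mean[i], tab$day6_mean[i], tab$day7_mean[i]))
  }, numeric(1))
  consistent <- c("MT3dCT", "MT3dNT", "MT1E", "MT1E-CT", "MT1E-NT",
                  "blank_vector")
  idx <- tab$cell_line %in% consistent
  expect_equal(combined[idx], tab$combined_printed[idx])
  # the two known-discrepant rows stay flagged, never silently matched
  expect_false(combined[tab$cell_line == "MT3"] ==
                 tab$combined_printed[tab$cell_line == "MT3"])
  expect_false(combined[tab$cell_line == "parent"] ==
                 tab$combined_printed[tab$cell_line == "parent"])
})

test_that("dome-expression association: exhaustive rank-sum permutation", {
  # perfect separation, 3 positive vs 5 negative: minimal p = 1/C(8,3)
  pheno <- tibble::tibble(
    cell_line = letters[1:8],
    dome_positive = c(rep(TRUE, 3), rep(FALSE, 5)),
    set_expression = c(10, 9, 8, 5, 4, 3, 2, 1))
  res <- dome_geneset_association(pheno)
  expect_equal(res$p_value, 1 / choose(8, 3))
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_assignments, choose(8, 3))

  # brute-force oracle on a non-degenerate configuration
  pheno2 <- pheno
  pheno2$set_expression <- c(7, 2, 9, 5, 4, 8, 1, 3)
  res2 <- dome_geneset_association(pheno2)
  r <- rank(pheno2$set_expression)
  ws <- apply(utils::combn(8, 3), 2, function(idx) sum(r[idx]))
  expect_equal(res2$p_value, mean(ws >= sum(r[1:3]) - 1e-12))

  # identical expression in every line: p = 1
  flat <- dplyr::mutate(pheno, set_expression = 5)
  expect_equal(dome_geneset_association(flat)$p_value, 1)

  expect_error(dome_geneset_association(dplyr::mutate(pheno, dome_positive = TRUE)),
               "both phenotype classes")
})

test_that("association p-values are uniform under the null", {
  set.seed(33)
  ps <- replicate(400, {
    pheno <- tibble::tibble(cell_line = letters[1:8],
                            dome_positive = sample(c(rep(TRUE, 3), rep(FALSE, 5))),
                            set_expression = rnorm(8))
    dome_geneset_association(pheno)$p_value
  })
  # exhaustive one-sided p on 56 assignments: P(p <= t) <= t for all t
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 400) + 1 / 56)
  }
  expect_gt(mean(ps), 0.4)
})

test_that("dome-positive CT-only lines rank above NT lines on planted expression", {
  cfg <- sim_config(n_probes = 400, planted_block_size = 12, seed = 44)
  sim <- simulate_expression(cfg)
  block <- attr(sim$truth, "block")
  keep <- dplyr::filter(sim$samples, !.data$is_reference)
  expr_block <- dplyr::filter(sim$expression, .data$probe_id %in% block)
  per_line <- keep |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(
      set_expression = mean(log(as.matrix(expr_block[, .data$array_id]))),
      has_ct = .data$has_ct[1], has_nt = .data$has_nt[1], .groups = "drop")
  ct_only <- per_line$set_expression[per_line$has_ct & !per_line$has_nt]
  nt <- per_line$set_expression[per_line$has_nt]
  expect_true(min(ct_only) > max(nt))

  pheno <- tibble::tibble(cell_line = per_line$cell_line,
                          dome_positive = per_line$has_ct & !per_line$has_nt,
                          set_expression = per_line$set_expression)
  res <- dome_geneset_association(pheno)
  expect_equal(res$p_value, 1 / choose(7, 2))
})
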
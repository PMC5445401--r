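test_that("overlap distance evaluates the set-overlap formula", {
  expect_equal(overlap_distance(c("p1", "p2", "p3"), c("p2", "p3", "p4")), 0.5)
  expect_equal(overlap_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(overlap_distance("a", "b"), 1)
  expect_equal(overlap_distance(character(), "a"), 1)
  expect_warning(d0 <- overlap_distance(character(), character()), "both sets empty")
  expect_equal(d0, 0)
})

test_that("overlap distance is a metric on random sets", {
  set.seed(404)
  for (i in 1:300) {
    a <- random_gene_set(); b <- random_gene_set(); c <- random_gene_set()
    if (!length(a) || !length(b) || !length(c)) next
    dab <- overlap_distance(a, b)
    expect_equal(dab, overlap_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(overlap_distance(a, a), 0)
    if (dab == 0) expect_setequal(a, b)
    expect_lte(dab, overlap_distance(a, c) + overlap_distance(c, b) + 1e-12)
  }
})

test_that("overlap distance agrees with an independent binary Jaccard implementation", {
  skip_if_not_installed("vegan")
  set.seed(55)
  universe <- paste0("g", 1:40)
  for (i in 1:50) {
    a <- sample(universe, sample(1:20, 1))
    b <- sample(universe, sample(1:20, 1))
    inc <- rbind(as.integer(universe %in% a), as.integer(universe %in% b))
    oracle <- as.numeric(vegan::vegdist(inc, method = "jaccard", binary = TRUE))
    expect_equal(overlap_distance(a, b), oracle)
  }
})

test_that("distance_matrix assembles labelled symmetric matrices", {
  sets <- tibble::tibble(
    array_id = rep(c("s1", "s2", "s3"), times = c(2, 2, 2)),
    probe_id = c("1", "2", "2", "3", "5", "6"))
  D <- gene_set_distance(sets)
  expect_equal(D["s1", "s2"], 1 - 1 / 3)
  expect_equal(D["s1", "s3"], 1)
  expect_equal(D["s2", "s3"], 1)
  expect_equal(diag(D), c(s1 = 0, s2 = 0, s3 = 0))

  same <- tibble::tibble(array_id = rep(c("x", "y", "z"), each = 2),
                         probe_id = rep(c("1", "2"), 3))
  expect_true(all(gene_set_distance(same) == 0))

  expect_error(gene_set_distance(sets[1:2, ]), ">= 2 gene sets")
  expect_error(gene_set_distance(sets, set_ids = c("s1", "s1")), "duplicate")
})

test_that("ward heights follow the Lance-Williams recurrence (hand oracle)", {
  # two leaves: single merge at their distance, both variants
  D2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (v in c("ward.D2", "ward.D")) {
    tr <- ward_agglomerate(D2, variant = v)
    expect_equal(tr$height, 0.7)
    expect_equal(tr$merge, matrix(c(-1L, -2L), 1))
  }

  # three leaves, D(1,2)=0.1, D(1,3)=D(2,3)=1: hand-applied recurrence gives
  # ward.D:  d({1,2},3) = (2*1 + 2*1 - 1*0.1)/3 = 1.3
  # ward.D2: on squares, (2*1 + 2*1 - 0.01)/3 = 1.33; height = sqrt(1.33)
  D3 <- matrix(c(0, .1, 1, .1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  trD <- ward_agglomerate(D3, variant = "ward.D")
  expect_equal(trD$height, c(0.1, 1.3))
  trD2 <- ward_agglomerate(D3, variant = "ward.D2")
  expect_equal(trD2$height, c(0.1, sqrt(3.99 / 3)))
  expect_equal(trD2$merge, matrix(c(-1L, -3L, -2L, 1L), 2))
})

test_that("ward agglomeration matches the reference implementation merge-for-merge", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    D <- random_distance_matrix(n)
    for (v in c("ward.D2", "ward.D")) {
      mine <- ward_agglomerate(D, variant = v)
      ref <- stats::hclust(stats::as.dist(D), method = v)
      expect_equal(mine$merge, ref$merge)
      expect_equal(mine$height, ref$height, tolerance = 1e-10)
    }
  }
})

test_that("cut_tree produces deterministic k-cluster partitions", {
  set.seed(5)
  D <- random_distance_matrix(6)
  tr <- ward_agglomerate(D)
  all_own <- cut_tree(tr, 6)
  expect_equal(sort(unique(all_own$cluster)), 1:6)
  one <- cut_tree(tr, 1)
  expect_true(all(one$cluster == 1L))
  expect_error(cut_tree(tr, 0), "k")
  expect_error(cut_tree(tr, 7), "k")
  expect_identical(cut_tree(tr, 3), cut_tree(tr, 3))
})

test_that("newick export uses midpoint branch lengths and parses back", {
  D <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_newick(ward_agglomerate(D)), "(a:0.2,b:0.2);")

  skip_if_not_installed("ape")
  set.seed(12)
  D5 <- random_distance_matrix(5)
  tr <- ward_agglomerate(D5)
  phy <- ape::read.tree(text = to_newick(tr))
  expect_setequal(phy$tip.label, rownames(D5))
  # ultrametric under the midpoint convention: all tips at depth h_root/2
  depths <- ape::node.depth.edgelength(phy)[seq_len(5)]
  expect_equal(depths, rep(max(tr$height) / 2, 5), tolerance = 1e-8)

  D3 <- matrix(c(0, .1, 1, .1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  nwk <- to_newick(ward_agglomerate(D3))
  expect_match(nwk, "^\\(\\(.*\\):.*,c:.*\\);$|^\\(c:.*,\\(.*\\):.*\\);$")
})

test_that("planted two-group structure is recovered by the k=2 cut", {
  cfg <- sim_config(n_probes = 800, planted_block_size = 16, ct_effect = 4,
                    nt_effect = 0.25, noise_log_sd = 0.3, seed = 21)
  sim <- simulate_expression(cfg)
  sets <- build_gene_sets(sim$expression, sim$samples, mode = "signed")
  flagged <- sim$samples$array_id[sim$samples$has_ct | sim$samples$has_nt]
  D <- gene_set_distance(sets, set_ids = intersect(attr(sets, "set_ids"), flagged))
  cl <- cut_tree(ward_agglomerate(D), 2)
  truth <- sim$samples$has_nt[match(cl$array_id, sim$samples$array_id)]
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
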
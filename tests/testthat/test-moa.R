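# Pearson distance, UPGMA clustering, MoA assignment, Newick, heat map.

test_that("Pearson distance matches the textbook formula and its bounds", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 4))
  d <- pearson_distance_matrix(m)
  expect_equal(d["a", "b"], 1 - oracle_pearson(c(1, 2, 3), c(1, 2, 4)),
               tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))

  m2 <- rbind(x = c(1, -2, 3, 0), y = c(1, -2, 3, 0), z = -c(1, -2, 3, 0))
  d2 <- pearson_distance_matrix(m2)
  expect_equal(d2["x", "y"], 0)            # identical profiles
  expect_equal(d2["x", "z"], 2)            # negation: r = -1
  expect_true(all(d2 >= 0 & d2 <= 2))
  expect_equal(d2, t(d2))

  expect_error(pearson_distance_matrix(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance.*a")
  mm <- rbind(a = c(1, 2, NA, NA), b = c(NA, 2, 3, 4))
  expect_error(pearson_distance_matrix(mm), "fewer than 3")
})

test_that("UPGMA agrees with a brute-force agglomerator", {
  # two samples: a single merge at their distance
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- hierarchical_cluster(d2)
  expect_equal(tr2$hclust$height, 0.4)

  # three samples, hand-traced: (A,B) at .1, then C at .9
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr3 <- hierarchical_cluster(d3)
  expect_equal(sort(tr3$hclust$height), c(0.1, 0.9))
  expect_equal(unname(sort(unlist(stats::cutree(tr3$hclust, k = 2)[c("A", "B")]))),
               c(1, 1))

  # random 3-6 leaf matrices vs the O(n^3) oracle, via cophenetic heights
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:6, 1)
    d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
    d <- d + t(d)
    tree <- hierarchical_cluster(d)
    got <- as.matrix(stats::cophenetic(tree$hclust))
    want <- oracle_upgma_cophenetic(d)
    expect_lt(max(abs(got[rownames(want), colnames(want)] - want)), 1e-10)
  }

  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(hierarchical_cluster(matrix(c(0, -1, -1, 0), 2)),
               "non-negative")
})

test_that("leaf order puts the tighter subtree first", {
  d3 <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- hierarchical_cluster(d3)
  # at the root the single leaf C (height 0) is tighter than the (A,B)
  # subtree (height 0.1); within (A,B) the tie breaks on leaf index
  expect_equal(tr$labels[tr$order], c("C", "A", "B"))
})

test_that("tree cut at the planted class count recovers the classes", {
  lib <- generate_reference_library("core", n_compounds = 60,
                                    n_moa_classes = 6, noise_sd = 0.05,
                                    seed = 7)
  tree <- hierarchical_cluster(pearson_distance_matrix(lib$profiles))
  cl <- cut_tree(tree, k = 6)
  expect_equal(adjusted_rand_index(cl, lib$labels$moa_label), 1)
})

test_that("MoA assignment follows the majority/tie/unassigned rules", {
  lib <- generate_reference_library("core", n_compounds = 40,
                                    n_moa_classes = 4, noise_sd = 0.1,
                                    seed = 5)
  # a fraction identical to one reference joins its class with r = 1
  frac <- lib$profiles[1, , drop = FALSE]
  rownames(frac) <- "FRAC1"
  mat <- rbind(lib$profiles, frac)
  tree <- hierarchical_cluster(pearson_distance_matrix(mat))
  labels <- setNames(lib$labels$moa_label, lib$labels$compound_id)
  calls <- assign_moa(tree, mat, labels, h = 0.3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$predicted_moa, lib$labels$moa_label[1])
  expect_equal(calls$nearest_r, 1, tolerance = 1e-12)
  expect_true(calls$support > 0 && calls$support <= 1)

  # an anti-correlated fraction lands in a references-free cluster
  anti <- -lib$profiles[1, , drop = FALSE]
  rownames(anti) <- "FRAC2"
  mat2 <- rbind(lib$profiles, anti)
  tree2 <- hierarchical_cluster(pearson_distance_matrix(mat2))
  calls2 <- assign_moa(tree2, mat2, labels, h = 0.3)
  expect_equal(calls2$predicted_moa, "unassigned")

  # a cut that leaves one all-encompassing cluster warns but still calls
  expect_warning(assign_moa(tree, mat, labels, h = 2.1), "single cluster")
})

test_that("assignment accuracy decays with noise and dies under permutation", {
  lib <- generate_reference_library("core", n_compounds = 100,
                                    n_moa_classes = 10, noise_sd = 0.1,
                                    seed = 11)
  labels <- setNames(lib$labels$moa_label, lib$labels$compound_id)
  acc <- numeric(0)
  for (sdev in c(0.05, 0.15, 0.3, 0.6)) {
    truth <- rep(colnames(lib$class_effects), length.out = 30)
    frac <- planted_profiles(lib$class_effects, truth, sdev, seed = 100 + sdev * 100)
    mat <- rbind(lib$profiles, frac)
    tree <- hierarchical_cluster(pearson_distance_matrix(mat))
    calls <- suppressWarnings(assign_moa(tree, mat, labels, k = 10))
    acc <- c(acc, mean(calls$predicted_moa == truth))
  }
  expect_true(all(diff(acc) <= 0.05))   # monotone non-increasing (small slack)
  expect_gt(acc[1], 0.9)

  # feature-shuffled fractions lose signature alignment: support ~ chance
  truth <- rep(colnames(lib$class_effects), length.out = 30)
  frac <- planted_profiles(lib$class_effects, truth, 0.15, seed = 42)
  frac_shuf <- frac[, withr::with_seed(43, sample(ncol(frac)))]
  colnames(frac_shuf) <- colnames(frac)
  mat <- rbind(lib$profiles, frac_shuf)
  tree <- hierarchical_cluster(pearson_distance_matrix(mat))
  calls <- suppressWarnings(assign_moa(tree, mat, labels, h = 0.3))
  k <- ncol(lib$class_effects)
  expect_lte(mean(calls$support), 1 / k + 0.1)
})

test_that("Newick export is exact, parseable and quote-safe", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(export_newick(hierarchical_cluster(d2)), "(A:0.2,B:0.2);")

  # round trip: ape-parsed cophenetic distances match the merge heights
  skip_if_not_installed("ape")
  lib <- generate_reference_library("core", n_compounds = 12,
                                    n_moa_classes = 3, noise_sd = 0.2,
                                    seed = 9)
  tree <- hierarchical_cluster(pearson_distance_matrix(lib$profiles))
  ph <- ape::read.tree(text = export_newick(tree))
  got <- ape::cophenetic.phylo(ph)   # leaf-to-leaf path = merge height
  want <- as.matrix(stats::cophenetic(tree$hclust))
  expect_lt(max(abs(got[rownames(want), colnames(want)] - want)), 1e-9)

  d2s <- d2
  dimnames(d2s) <- list(c("cmpd A", "B"), c("cmpd A", "B"))
  expect_match(export_newick(hierarchical_cluster(d2s)), "'cmpd A'",
               fixed = TRUE)
})

test_that("heat-map ordering follows the tree and spans the score range", {
  lib <- generate_reference_library("core", n_compounds = 10,
                                    n_moa_classes = 2, noise_sd = 0.2,
                                    seed = 2)
  tree <- hierarchical_cluster(pearson_distance_matrix(lib$profiles))
  tsv <- tempfile(fileext = ".tsv")
  ordered <- render_heatmap(lib$profiles, tree, tsv = tsv)
  expect_equal(rownames(ordered), tree$labels[tree$order])
  back <- as.data.frame(data.table::fread(tsv))
  expect_equal(back$sample_id, tree$labels[tree$order])

  zeros <- matrix(0, 4, 21,
                  dimnames = list(paste0("z", 1:4), core_panel()$feature_id))
  ztree <- hierarchical_cluster(matrix(0.5, 4, 4,
                                       dimnames = list(paste0("z", 1:4),
                                                       paste0("z", 1:4))) -
                                  diag(0.5, 4))
  tsv0 <- tempfile(fileext = ".tsv")
  render_heatmap(zeros, ztree, tsv = tsv0)
  z <- as.matrix(as.data.frame(data.table::fread(tsv0))[, -1])
  expect_true(all(z == 0))
})
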
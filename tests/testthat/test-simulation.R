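test_that("Yule trees are reproducible, ultrametric, and rescalable", {
  t1 <- simulate_yule_tree(50, seed = 1)
  t2 <- simulate_yule_tree(50, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-9))
  t3 <- simulate_yule_tree(40, seed = 2, height = 123)
  expect_equal(max(ape::node.depth.edgelength(t3)), 123)
  expect_error(simulate_yule_tree(1), ">= 2")
})

test_that("species pools are uniform draws with matching pruned trees", {
  tr <- simulate_yule_tree(30, seed = 3)
  full <- sample_species_pool(tr, 30, seed = 4)
  expect_setequal(full$species, tr$tip.label)
  pool <- sample_species_pool(tr, 10, seed = 5)
  expect_setequal(pool$tree$tip.label, pool$species)
  draws <- vapply(1:10, function(i)
    paste(sort(sample_species_pool(tr, 10, seed = i)$species), collapse = ","),
    character(1))
  expect_gt(length(unique(draws)), 1L)
  expect_error(sample_species_pool(tr, 31), "exceeds")
})

test_that("community matrices respect richness bounds and unit row sums", {
  pool <- paste0("sp", 1:40)
  m <- generate_community_matrix(pool, c(10L, 20L), n_sites = 240, seed = 6)
  S <- rowSums(m > 0)
  expect_true(all(S >= 10 & S <= 20))
  expect_equal(unname(rowSums(m)), rep(1, 240), tolerance = 1e-12)
  m5 <- generate_community_matrix(pool, c(5L, 5L), n_sites = 30, seed = 7)
  expect_true(all(rowSums(m5 > 0) == 5))
  expect_identical(generate_community_matrix(pool, c(3L, 8L), 20, seed = 8),
                   generate_community_matrix(pool, c(3L, 8L), 20, seed = 8))
  expect_error(generate_community_matrix(pool, c(10L, 50L), 10), "exceeds pool")
})

test_that("depth cuts partition tips into monophyletic clades", {
  tr <- fixture_tree()
  map <- clade_map_from_tree(tr, 1.5)
  expect_equal(unname(map[c("A", "B")]), rep(map[["A"]], 2))
  expect_false(map[["C"]] == map[["A"]])
  expect_equal(length(unique(map)), 2L)
  # cut just above the tips: every tip its own clade
  fine <- clade_map_from_tree(tr, 1e-6)
  expect_equal(length(unique(fine)), 3L)
  # just below the root every lineage still present there is a clade,
  # i.e. as many clades as the root has child lineages
  near_root <- clade_map_from_tree(tr, 2 - 1e-6)
  expect_equal(length(unique(near_root)), 2L)
  expect_error(clade_map_from_tree(tr, 2.5), "between 0 and the tree height")
  expect_error(clade_map_from_tree(tr, 0), "between 0 and the tree height")
  # clades are monophyletic: same-clade pairs are closer than the cut allows
  big <- simulate_yule_tree(40, seed = 9, height = 10)
  cm <- clade_map_from_tree(big, 4)
  d <- pairwise_distances(big)
  same <- outer(cm, cm, "==")
  expect_true(all(d[same & upper.tri(d)] < 2 * 4 + 1e-9))
  expect_true(all(d[!same & upper.tri(d)] >= 2 * 4 - 1e-9))
})

test_that("deep-branch stretching preserves shallow structure and clade maps", {
  tr <- simulate_yule_tree(30, seed = 10, height = 100)
  st <- stretch_tree_above(tr, 30, 300)
  expect_true(ape::is.ultrametric(st, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(st)), 300)
  expect_identical(clade_map_from_tree(tr, 30), clade_map_from_tree(st, 30))
  d0 <- pairwise_distances(tr); d1 <- pairwise_distances(st)
  shallow <- d0 < 2 * 30
  expect_equal(d1[shallow], d0[shallow], tolerance = 1e-9)
  expect_equal(d1[!shallow] - 2 * 30, (d0[!shallow] - 2 * 30) * (270 / 70),
               tolerance = 1e-9)
})

test_that("a toy factorial produces one result row per design cell", {
  cfg <- sim_config(scales = list(s1 = list(n_tips = 60L, height = 120)),
                    pool_sizes = 30L,
                    richness_ranges = list(c(3L, 8L)),
                    n_matrices_per_cell = 2L, n_sites = 30L,
                    clade_cut_depth = 40, master_seed = 2L)
  sim <- suppressMessages(run_factorial(cfg))
  expect_equal(nrow(sim$results), 2L)
  expect_true(all(c("r2_richness", "r2_divergence", "r2_regularity") %in%
                    colnames(sim$results)))
  expect_true(all(stats::complete.cases(
    sim$results[, c("r2_richness", "r2_divergence", "r2_regularity")])))
  # same master seed, same table
  sim2 <- suppressMessages(run_factorial(cfg))
  expect_identical(sim$results, sim2$results)
})

test_that("design cells carry collision-free derived seeds at reference scale", {
  cfg <- sim_config(master_seed = 17L) # full 3 x 3 x 6 x 50 reference design
  plan <- run_factorial(cfg, compute = "plan")
  expect_equal(nrow(plan$results), 2700L)
  expect_equal(as.vector(table(plan$results$scale)), rep(900L, 3L))
  expect_false(anyDuplicated(plan$results$seed) > 0)
})

test_that("matrices-only runs record per-cell richness and row-sum summaries", {
  cfg <- sim_config(scales = list(s1 = list(n_tips = 50L, height = 120),
                                  s2 = list(n_tips = 50L, height = 240)),
                    pool_sizes = c(30L, 20L),
                    richness_ranges = list(c(2L, 5L), c(5L, 10L)),
                    n_matrices_per_cell = 3L, n_sites = 25L,
                    clade_cut_depth = 40, master_seed = 3L)
  sim <- run_factorial(cfg, compute = "matrices")
  expect_equal(nrow(sim$results), 2L * 2L * 2L * 3L)
  expect_true(all(sim$results$n_sites == 25L))
  expect_true(all(sim$results$max_rowsum_err < 1e-12))
  lo <- sim$results$richness_range == "2-5"
  expect_true(all(sim$results$S_min[lo] >= 2 & sim$results$S_max[lo] <= 5))
  expect_true(all(sim$results$S_min[!lo] >= 5 & sim$results$S_max[!lo] <= 10))
})

test_that("YAML configs round-trip into the factorial runner", {
  dir <- withr::local_tempdir()
  cfgy <- file.path(dir, "sim.yaml")
  writeLines(c(
    "scales:",
    "  toy: {n_tips: 40, height: 120}",
    "pool_sizes: [20]",
    "richness_ranges:",
    "  - [3, 6]",
    "n_matrices_per_cell: 2",
    "n_sites: 20",
    "clade_cut_depth: 40",
    "master_seed: 5"), cfgy)
  cfg <- read_sim_config(cfgy)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_sites, 20L)
  sim <- suppressMessages(run_factorial(cfg, out_dir = file.path(dir, "run")))
  expect_true(file.exists(file.path(dir, "run", "results_r2.tsv")))
  expect_true(file.exists(file.path(dir, "run", "manifest.json")))
  tab <- utils::read.table(file.path(dir, "run", "results_r2.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2L)
})
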
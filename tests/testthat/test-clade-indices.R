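pool_of <- function(cr, s_sp = sum(cr)) {
  # assemble a pool summary from clade richness counts via a synthetic map
  sp <- unlist(mapply(function(cl, n) rep(cl, n), names(cr), cr,
                      SIMPLIFY = FALSE))
  map <- stats::setNames(sp, paste0("sp", seq_along(sp)))
  summarize_pool(map)
}

test_that("summarize_pool counts clades and species", {
  cr <- c(w = 4L, x = 3L, y = 2L, z = 1L)
  pool <- pool_of(cr)
  expect_equal(pool$CR_SP, 4L)
  expect_equal(pool$S_SP, 10L)
  expect_equal(pool$clade_richness[names(cr)], cr)
  single <- summarize_pool(c(a = "only", b = "only"))
  expect_equal(single$CR_SP, 1L)
  expect_error(summarize_pool(c(a = "f1"), pool_species = c("a", "ghost")),
               "ghost")
})

test_that("clade proportions aggregate covers and always sum to one", {
  cm <- c(A = "f1", B = "f1", C = "f2")
  pool <- summarize_pool(cm)
  p <- clade_proportions(c(A = 30, B = 30, C = 40), cm, pool)
  expect_equal(p, c(f1 = 0.6, f2 = 0.4))
  p1 <- clade_proportions(c(C = 5), cm, pool)
  expect_equal(p1, c(f1 = 0, f2 = 1))
  for (i in 1:20) {
    set.seed(7000 + i)
    ab <- stats::setNames(stats::runif(3), c("A", "B", "C"))
    expect_equal(sum(clade_proportions(ab, cm, pool)), 1)
  }
  expect_error(clade_proportions(c(A = 0), cm, pool), "zero total")
})

test_that("clade richness index reproduces its worked arithmetic", {
  p1 <- summarize_pool(c(a = "f1"))
  expect_equal(clade_richness_index(1, c(f1 = 1), p1), 3)

  pool <- structure(list(clade_richness = c(f1 = 10L, f2 = 2L), CR_SP = 2L,
                         S_SP = 12L), class = "clade_pool")
  expect_equal(clade_richness_index(4, c(f1 = 0.6, f2 = 0.4), pool),
               log(4) + 3 * (0.06 + 0.2))
  expect_equal(clade_richness_index(4, c(f1 = 0.6, f2 = 0.4), pool),
               2.166294, tolerance = 1e-6)

  pool2 <- structure(list(clade_richness = c(f1 = 50L, f2 = 5L), CR_SP = 2L,
                          S_SP = 55L), class = "clade_pool")
  lop <- clade_richness_index(10, c(f1 = 0.9, f2 = 0.1), pool2)
  bal <- clade_richness_index(10, c(f1 = 0.5, f2 = 0.5), pool2)
  expect_equal(lop, 2.416585, tolerance = 1e-6)
  expect_equal(bal, 2.632585, tolerance = 1e-6)
  expect_lt(lop, bal) # moving cover to the species-poor clade raises the index
  expect_error(clade_richness_index(0, c(f1 = 1, f2 = 0), pool2), ">= 1")
})

test_that("clade divergence index is exactly one at uniform proportions", {
  pool <- pool_of(c(w = 4L, x = 3L, y = 2L, z = 1L))
  expect_identical(clade_divergence_index(
    c(w = 0.25, x = 0.25, y = 0.25, z = 0.25), pool), 1)
  expect_equal(clade_divergence_index(c(w = 1, x = 0, y = 0, z = 0), pool), 0.25)
  expect_equal(clade_divergence_index(c(w = 0.5, x = 0.5, y = 0, z = 0), pool), 0.75)
})

test_that("clade regularity index is exactly one at richness-proportional cover", {
  pool <- pool_of(c(w = 4L, x = 3L, y = 2L, z = 1L))
  expect_identical(clade_regularity_index(
    c(w = 0.4, x = 0.3, y = 0.2, z = 0.1), pool), 1)
  expect_equal(clade_regularity_index(
    c(w = 0.4, x = 0.3, y = 0.3, z = 0), pool), 0.98)
  # extreme concentration on the rarest clade drives the index negative
  expect_equal(clade_regularity_index(c(w = 0, x = 0, y = 0, z = 1), pool), -0.1)
})

test_that("divergence index is strictly positive on random simplex draws", {
  for (i in 1:50) {
    set.seed(8000 + i)
    k <- sample(2:12, 1)
    cr <- stats::setNames(sample(1:9, k, replace = TRUE), paste0("c", 1:k))
    pool <- pool_of(cr)
    raw <- stats::runif(k)
    # random proportions, possibly with absent clades
    raw[sample(k, sample(0:(k - 1), 1))] <- 0
    if (sum(raw) == 0) raw[1] <- 1
    p <- stats::setNames(raw / sum(raw), names(cr))
    cdi <- clade_divergence_index(p, pool)
    expect_gt(cdi, 0)
    expect_lte(cdi, 1)
    expect_lte(clade_regularity_index(p, pool), 1)
  }
})

test_that("richness index rises with S and with cover moved to poorer clades", {
  for (i in 1:20) {
    set.seed(8500 + i)
    k <- sample(2:8, 1)
    cr <- stats::setNames(sample(1:20, k), paste0("c", 1:k))
    pool <- pool_of(cr)
    raw <- stats::runif(k) + 0.01
    p <- stats::setNames(raw / sum(raw), names(cr))
    s <- sample(2:20, 1)
    expect_gt(clade_richness_index(s + 1, p, pool),
              clade_richness_index(s, p, pool))
    # shift mass from the richest to the poorest clade
    rich <- names(which.max(cr)); poor <- names(which.min(cr))
    q <- p
    shift <- p[rich] / 2
    q[rich] <- q[rich] - shift; q[poor] <- q[poor] + shift
    expect_gt(clade_richness_index(s, q, pool),
              clade_richness_index(s, p, pool))
  }
})

test_that("index table matches the chained single-site computation", {
  # one species in a singleton clade of a 2-clade, 10-species pool
  sp <- c(paste0("r", 1:9), "lone")
  map <- stats::setNames(c(rep("big", 9), "small"), sp)
  comm <- matrix(0, 2, 10, dimnames = list(c("s1", "s2"), sp))
  comm[1, "lone"] <- 5
  comm[2, ] <- 1
  pool <- summarize_pool(map)
  idx <- clade_index_table(comm, map, pool = pool)
  expect_equal(idx$clade_richness_index[1], 3)
  expect_equal(idx$clade_divergence_index[1], 0.5)
  expect_equal(idx$clade_regularity_index[1], 1 - (0.81 + 0.81))
  # vectorized table equals the per-site operations
  for (s in 1:2) {
    p <- clade_proportions(comm[s, ], map, pool)
    expect_equal(idx$clade_richness_index[s],
                 clade_richness_index(idx$S[s], p, pool))
    expect_equal(idx$clade_divergence_index[s], clade_divergence_index(p, pool))
    expect_equal(idx$clade_regularity_index[s], clade_regularity_index(p, pool))
  }
})

test_that("indices depend on abundances only through proportions", {
  map <- stats::setNames(rep(c("f1", "f2", "f3"), times = c(3, 2, 1)),
                         paste0("sp", 1:6))
  comm <- matrix(stats::runif(12, 0, 10), 2, 6,
                 dimnames = list(c("s1", "s2"), names(map)))
  idx1 <- clade_index_table(comm, map)
  idx2 <- clade_index_table(comm * 37.5, map)
  expect_equal(idx1, idx2)
})

test_that("finer clade maps slot in with no other change", {
  sp <- paste0("sp", 1:8)
  coarse <- stats::setNames(rep(c("o1", "o2"), each = 4), sp)
  fine <- stats::setNames(rep(c("f1", "f2", "f3", "f4"), each = 2), sp)
  set.seed(42)
  comm <- matrix(stats::runif(16), 2, 8, dimnames = list(c("s1", "s2"), sp))
  ic <- clade_index_table(comm, coarse)
  iff <- clade_index_table(comm, fine)
  expect_equal(colnames(ic), colnames(iff))
  expect_false(isTRUE(all.equal(ic$clade_divergence_index,
                                iff$clade_divergence_index)))
})

test_that("present-clades-only summation is available as a sensitivity switch", {
  pool <- pool_of(c(w = 2L, x = 2L))
  p <- c(w = 1, x = 0)
  expect_equal(clade_divergence_index(p, pool, absent = "include"),
               1 - (0.25 + 0.25))
  expect_equal(clade_divergence_index(p, pool, absent = "exclude"),
               1 - 0.25)
})
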
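test_that("reference-set construction is orthogonal, equal-magnitude, seeded", {
  rvs <- build_reference_set(k = 3, d = 65535, seed = 5)
  R <- rvs$R
  mags <- sqrt(colSums(R^2))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      cosang <- sum(R[, i] * R[, j]) / (mags[i] * mags[j])
      expect_lt(abs(cosang), 1e-10)
    }
  }
  expect_equal(mags / mags[1], rep(1, 3), tolerance = 1e-12)

  expect_identical(build_reference_set(3, 100, seed = 9)$R,
                   build_reference_set(3, 100, seed = 9)$R)
  expect_false(isTRUE(all.equal(build_reference_set(3, 100, seed = 1)$R,
                                build_reference_set(3, 100, seed = 2)$R)))
  expect_error(build_reference_set(k = 3, d = 2, seed = 1), "at least k")
})

test_that("split keys are deterministic and injective", {
  t1 <- read_newick("((1,2),3,(4,5));", tm5)
  t2 <- read_newick("(3,(2,1),(5,4));", tm5)  # same topology, permuted text
  expect_identical(lapply(tree_splits(t1)$masks, split_key, n = 5L),
                   lapply(tree_splits(t2)$masks, split_key, n = 5L))
  idx <- split_indexer(5)
  keys <- lapply(idx$masks, split_key, n = 5L)
  expect_length(unique(keys), 10L)
  # stated serialization: n then sorted 0-based side indices, 4-byte big-endian
  m <- canonical_split(4:5, 5)
  expect_identical(split_key(m, 5L),
                   as.raw(c(0, 0, 0, 5, 0, 0, 0, 3, 0, 0, 0, 4)))
})

test_that("toy modulo-3 entries match the printed slot table", {
  toy <- toy_modulo3_set()
  ms <- function(sides) make_split_set(sides, tm5)$masks
  expect_equal(reference_entries(toy, ms(list(c("1", "2"))), 5)[1, ],
               c(1.0, 0.9))
  expect_equal(reference_entries(toy, ms(list(c("4", "5"))), 5)[1, ],
               c(1.0, 0.9))  # 4 + 5 = 9, 9 mod 3 = 0
  expect_equal(reference_entries(toy, ms(list(c("1", "4"))), 5)[1, ],
               c(-0.8, -0.8))  # 5 mod 3 = 2
})

test_that("projection reproduces both printed worked examples", {
  t <- read_newick("((1,2),3,(4,5));", tm5)
  fig5 <- explicit_reference_set(list(c("1", "2"), c("4", "5")),
                                 rbind(c(1.0, 0.9), c(-0.3, 0.6)), tm5)
  expect_identical(project(t, fig5), c(0.7, 1.5))
  expect_identical(project(t, toy_modulo3_set()), c(2.0, 1.8))
  # a 3-taxon star has no nontrivial splits: the origin
  star <- read_newick("(1,2,3);")
  expect_identical(project(star, build_reference_set(3, 11, seed = 1)),
                   c(0, 0, 0))
})

test_that("batch projection is order-preserving and linear", {
  trees <- enumerate_trees(tm5)
  toy <- toy_modulo3_set()
  pts <- project_batch(trees, toy)
  expect_equal(nrow(pts), 15L)
  for (i in c(1, 7, 15)) {
    expect_equal(unlist(pts[i, c("x", "y")]), project(trees[[i]], toy),
                 ignore_attr = TRUE)
  }
  # linearity: the projection is the sum of per-split entries
  for (t in trees[c(2, 9)]) {
    masks <- tree_splits(t)$masks
    e <- reference_entries(toy, masks, 5)
    expect_equal(project(t, toy), colSums(e))
  }
  # the images lie among the 6 candidate sums of two slot vectors
  sums <- unique(round(cbind(pts$x, pts$y), 10))
  cand <- NULL
  for (i in 1:3) {
    for (j in i:3) cand <- rbind(cand, toy$R[i, ] + toy$R[j, ])
  }
  expect_equal(nrow(unique(round(cand, 10))), 6L)
  expect_true(all(apply(sums, 1, function(p) {
    any(abs(cand[, 1] - p[1]) + abs(cand[, 2] - p[2]) < 1e-9)
  })))
  expect_equal(nrow(project_batch(list(), toy)), 0L)
})

test_that("hash projection equals the dense-matrix oracle exactly", {
  idx <- split_indexer(6)
  trees <- enumerate_trees(6)
  for (seed in c(1, 2)) {
    rvs <- build_reference_set(3, 257, seed = seed)
    for (t in trees[seq(1, 105, by = 7)]) {
      expect_identical(project(t, rvs), dense_project_oracle(t, rvs, idx))
    }
  }
})

test_that("projection is deterministic and taxon-map sensitive", {
  rvs <- build_reference_set(3, 65535, seed = 3)
  t <- read_newick("((1,2),3,(4,5));", tm5)
  expect_identical(project(t, rvs),
                   project(read_newick("((1,2),3,(4,5));", tm5), rvs))
  # relabeling taxa (different map) moves the point
  tm_perm <- taxon_map(as.character(c(2, 1, 3, 4, 5)), sort = FALSE)
  t_perm <- read_newick("((1,2),4,(3,5));", tm_perm)
  expect_false(isTRUE(all.equal(project(t, rvs), project(t_perm, rvs))))
})

test_that("diagnostics report rank, angles, occupancy and evenness", {
  for (seed in 1:5) {
    dg <- projection_diagnostics(build_reference_set(3, 65535, seed = seed), 8)
    expect_equal(dg$rank, 3L)
    expect_equal(sum(dg$f), dg$dim)
  }
  # a perfectly even hash (xi = 0) gives exactly equal magnitudes
  even <- hash_scheme("jenkins_oaat")
  even$fun <- function(masks, n, d) {
    idx <- split_indexer(n)
    (match(masks, idx$masks) - 1L) %% d
  }
  rvs <- build_reference_set(3, 5, seed = 4, scheme = even)
  dg <- projection_diagnostics(rvs, 5)  # dim 10 = 2 x 5 slots
  expect_equal(dg$xi, 0)
  expect_equal(dg$magnitude_ratios, rep(1, 3), tolerance = 1e-12)
  # Jenkins at full table size: near-orthogonal in practice.  The deviation
  # shrinks as split-space dimension grows relative to the table: a few
  # degrees while d' << d (n = 12: d' = 2035), under one degree by n = 16
  # (d' = 32751).
  dg12 <- projection_diagnostics(build_reference_set(3, 65535, seed = 1), 12)
  expect_true(all(abs(dg12$pairwise_angles - 90) < 5))
  dg16 <- projection_diagnostics(build_reference_set(3, 65535, seed = 1), 16)
  expect_true(all(abs(dg16$pairwise_angles - 90) < 1))
  expect_error(projection_diagnostics(build_reference_set(3, 17, seed = 1), 20),
               "16")
})

test_that("inversion recovers trees at a projected point", {
  rvs <- build_reference_set(3, 65535, seed = 6)
  t <- read_newick("((1,2),3,(4,5));", tm5)
  p <- project(t, rvs)
  hits <- invert_projection(p, rvs, tm5, tol = 1e-9)
  expect_true(any(vapply(hits, topo_equal, TRUE, b = t)))

  # toy scheme: the point (2.0, 1.8) is hit by every tree whose two splits
  # both hash to slot 0 — exhaustive enumeration oracle
  toy <- toy_modulo3_set()
  trees <- enumerate_trees(tm5)
  at_point <- Filter(function(t) {
    slots <- toy$scheme$fun(tree_splits(t)$masks, 5, 3)
    all(slots == 0L)
  }, trees)
  hits <- invert_projection(c(2.0, 1.8), toy, tm5, tol = 1e-9)
  expect_length(hits, length(at_point))
  keys <- function(ts) sort(vapply(ts, function(x) {
    paste(tree_splits(x)$masks, collapse = ".")
  }, ""))
  expect_identical(keys(hits), keys(at_point))

  # far away: empty
  expect_length(invert_projection(c(100, 100), toy, tm5, tol = 1e-9), 0L)

  # exhaustive regime extends through n = 8 and finds the source tree
  tm8 <- taxon_map(as.character(1:8), sort = FALSE)
  set.seed(2)
  t8 <- random_ntree(tm8)
  rvs8 <- build_reference_set(3, 65535, seed = 8)
  hits8 <- invert_projection(project(t8, rvs8), rvs8, tm8, tol = 1e-9)
  expect_true(any(vapply(hits8, topo_equal, TRUE, b = t8)))
  # beam regime is heuristic but sound: every returned tree projects within
  # tol of the target
  hits8b <- invert_projection(project(t8, rvs8), rvs8, tm8, tol = 1e-9,
                              beam = 128, exhaustive_max = 7L)
  for (h in hits8b) {
    expect_lt(sqrt(sum((project(h, rvs8) - project(t8, rvs8))^2)), 1e-9)
  }
})
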
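test_that("Tanimoto distance matches hand-enumerated cases and degenerate rules", {
  expect_equal(tanimoto_distance(c(1, 1, 1, 0), c(1, 1, 1, 0)), 0)
  expect_equal(tanimoto_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # on-bits {1,2,3} vs {2,3,4}: shared 2, union 4
  expect_equal(tanimoto_distance(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)), 0.5)
  expect_warning(d0 <- tanimoto_distance(c(0, 0, 0), c(0, 0, 0)), "degenerate")
  expect_equal(d0, 0)
  expect_equal(tanimoto_distance(c(0, 0, 0), c(1, 0, 0)), 1)
  expect_error(tanimoto_distance(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(tanimoto_distance(c(1, 2), c(1, 0)), "binary")
})

test_that("pairwise distance matrix equals the element-by-element oracle and is a bounded semimetric", {
  fps <- random_fps(10, 24, seed = 41)
  d <- pairwise_distances(fps)$d
  # brute-force double loop oracle via the scalar function
  for (i in 1:10) {
    for (j in 1:10) {
      expect_equal(d[i, j], tanimoto_distance(fps$bits[i, ], fps$bits[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(d >= 0 & d <= 1))
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 10))

  expect_error(pairwise_distances(fp_from_bits(list(1:2), 5)), "at least 2")
})

test_that("identical chemicals collapse to zero distance and one cluster", {
  fps <- fp_from_bits(rep(list(c(1, 3, 5)), 4), 8)
  d <- pairwise_distances(fps)
  expect_true(all(d$d == 0))
  for (v in c("ward_d2", "ward_d")) {
    expect_equal(length(unique(unclass(ward_cut(d, 0.5, v)))), 1L)
  }
})

test_that("ward cut separates two exactly-opposed blocks at height 1 in both dialects", {
  # two blocks of identical fingerprints, between-block distance 1:
  # within-block merges sit at height 0, the final merge above 1
  fps <- fp_from_bits(list(1:4, 1:4, 5:8, 5:8), 8,
                      chem_ids = c("A1", "A2", "B1", "B2"))
  d <- pairwise_distances(fps)
  for (v in c("ward_d2", "ward_d")) {
    a <- ward_cut(d, cut_height = 1, linkage_variant = v)
    expect_equal(length(unique(unclass(a))), 2L)
    expect_equal(as.integer(a), c(1L, 1L, 2L, 2L)) # blocks intact, ids by first appearance
  }
  # cut above the tree root: everything merges
  expect_equal(length(unique(unclass(ward_cut(d, cut_height = 100)))), 1L)
  expect_error(ward_cut(d, cut_height = 0), "positive")
})

test_that("cluster count is monotone non-increasing in cut height", {
  fps <- random_fps(40, 60, seed = 7)
  d <- pairwise_distances(fps)
  heights <- c(0.2, 0.5, 1, 1.5, 2, 3, 5)
  for (v in c("ward_d2", "ward_d")) {
    k <- vapply(heights, function(h) {
      length(unique(unclass(ward_cut(d, h, v))))
    }, integer(1))
    expect_true(all(diff(k) <= 0), info = v)
  }
})

test_that("partition is equivariant under permutation of input order", {
  u <- gen_universe(universe_spec(n_clusters = 5, cluster_sizes = 8, seed = 19))
  a1 <- ward_cut(pairwise_distances(u$fingerprints), 1)
  set.seed(99); perm <- sample(length(u$fingerprints$chem_ids))
  fps2 <- fp_subset(u$fingerprints, u$fingerprints$chem_ids[perm])
  a2 <- ward_cut(pairwise_distances(fps2), 1)
  # same partition as a set of sets (labels may differ)
  part <- function(a) unname(split(names(a), unclass(a)))
  canon <- function(p) sort(vapply(p, function(s) paste(sort(s), collapse = "|"), ""))
  expect_equal(canon(part(a1)), canon(part(a2)))
})

test_that("cluster size profile reports sizes, singletons and planted block sizes", {
  a <- assign_clusters(c("a", "b", "c"), c(1, 1, 2))
  prof <- cluster_size_profile(a)
  expect_equal(prof$sizes$size, c(2L, 1L))
  expect_equal(prof$n_singletons, 1L)
  expect_equal(prof$n_doubletons, 1L)
  expect_equal(prof$n_chemicals, 3L)

  sizes <- c(4, 6, 8, 10, 12)
  u <- gen_universe(universe_spec(n_clusters = 5, cluster_sizes = sizes, seed = 5))
  rec <- ward_cut(pairwise_distances(u$fingerprints), 1)
  expect_equal(sort(cluster_size_profile(rec)$sizes$size), sort(sizes))
})
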
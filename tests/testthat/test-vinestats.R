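test_that("wasserstein distance honors the diagonal matching rules", {
  d <- rbind(c(0, 2), c(1, 3))
  expect_equal(wasserstein_distance(d, d), 0)
  # single point vs empty: diagonal projection costs (death - birth) / 2
  expect_equal(wasserstein_distance(rbind(c(0, 2)), matrix(numeric(), 0, 2)), 1)
  expect_equal(wasserstein_distance(rbind(c(0, 2)), matrix(numeric(), 0, 2),
                                    q = 3), 1)
  # direct match (cost 2) beats the two-diagonal route (1 + 2 = 3)
  expect_equal(wasserstein_distance(rbind(c(0, 2)), rbind(c(0, 4)), q = 1), 2)
  # empty vs empty
  expect_equal(wasserstein_distance(matrix(numeric(), 0, 2),
                                    matrix(numeric(), 0, 2)), 0)
  expect_error(wasserstein_distance(d, d, q = 0.5), "q must be")
})

test_that("wasserstein matches the exhaustive-matching oracle", {
  set.seed(41)
  for (k in 1:200) {
    m1 <- random_diagram(sample(0:5, 1))
    m2 <- random_diagram(sample(0:5, 1))
    q <- sample(c(1, 2), 1)
    expect_equal(wasserstein_distance(m1, m2, q = q),
                 oracle_wasserstein(m1, m2, q = q), tolerance = 1e-9)
  }
})

test_that("wasserstein is a metric and feels feature presence", {
  set.seed(43)
  for (k in 1:25) {
    m1 <- random_diagram(sample(1:4, 1))
    m2 <- random_diagram(sample(1:4, 1))
    m3 <- random_diagram(sample(1:4, 1))
    w12 <- wasserstein_distance(m1, m2)
    expect_equal(w12, wasserstein_distance(m2, m1))
    expect_gte(w12 + wasserstein_distance(m2, m3) -
                 wasserstein_distance(m1, m3), -1e-9)
    expect_equal(wasserstein_distance(m1, m1), 0)
  }
  # adding a feature to one diagram strictly increases the distance
  m <- rbind(c(0, 2), c(1, 4))
  expect_gt(wasserstein_distance(rbind(m, c(0.5, 3)), m),
            wasserstein_distance(m, m))
})

test_that("truncated classes enter the distance at r_max", {
  d1 <- rbind(c(0.5, NA))
  d2 <- matrix(numeric(), 0, 2)
  expect_equal(wasserstein_distance(d1, d2, r_max = 4.5), 2)
  expect_error(wasserstein_distance(d1, d2), "r_max")
})

test_that("the group statistic is the summed within-group mean pairwise cost", {
  same <- replicate(5, rbind(c(0, 2)), simplify = FALSE)
  expect_equal(group_statistic(same, c("a", "a", "b", "b", "b")), 0)

  # group a all {(0,2)}, group b all empty: both internally identical
  mixed <- list(rbind(c(0, 2)), rbind(c(0, 2)),
                matrix(numeric(), 0, 2), matrix(numeric(), 0, 2))
  expect_equal(group_statistic(mixed, c("a", "a", "b", "b")), 0)

  # hand-computed at q = 1: group a pair (0,2)-(0,6) costs 4 (direct match
  # ties the double-diagonal route); group b pair (0,2)-(0,4) costs 2
  dg <- list(rbind(c(0, 2)), rbind(c(0, 6)), rbind(c(0, 2)), rbind(c(0, 4)))
  expect_equal(group_statistic(dg, c("a", "a", "b", "b"), q = 1), 4 + 2)

  expect_error(group_statistic(dg, c("a", "a", "a", "b")), "fewer than 2")
  expect_error(group_statistic(dg, c("a", "b", "c", "a")), "exactly two")
})

test_that("block permutation moves whole blocks of the tested conditions only", {
  des <- make_design(trs_per_block = 3,
                     cycle = c("enc", "con", "ret", "con"), n_cycles = 2)
  expect_equal(length(des$labels), 24L)
  set.seed(1)
  for (k in 1:25) {
    lab <- permute_labels_blockwise(des, c("enc", "ret"))
    # untested condition untouched
    expect_equal(lab == "con", des$labels == "con")
    # each original block keeps a single label (indices keep block membership)
    for (bi in seq_len(nrow(des$blocks)))
      expect_length(unique(lab[des$blocks$start[bi]:des$blocks$end[bi]]), 1L)
    # label multiset preserved
    expect_equal(sort(lab), sort(des$labels))
  }
  # 2 + 2 blocks admit choose(4, 2) = 6 assignments, all reachable
  set.seed(2)
  seen <- unique(replicate(300, paste(
    permute_labels_blockwise(des, c("enc", "ret")), collapse = "")))
  expect_equal(length(seen), 6L)

  one <- make_design(trs_per_block = 3, cycle = c("enc", "ret"), n_cycles = 1)
  expect_error(permute_labels_blockwise(one, c("enc", "ret")),
               "at least 2 blocks")

  # the reference acquisition admits choose(16, 8) = 12870 assignments
  expect_equal(choose(16, 8), 12870)
})

test_that("permutation test handles ties, seeds and label symmetry", {
  des <- make_design(trs_per_block = 2,
                     cycle = c("encoding", "consolidation",
                               "retrieval", "consolidation"), n_cycles = 3)
  # label-independent diagrams: every permuted statistic ties the observed
  same <- replicate(length(des$labels), rbind(c(0, 2)), simplify = FALSE)
  pt <- vine_permutation_test(same, des, n_perm = 99)
  expect_equal(pt$p.value, 1)

  set.seed(55)
  dgs <- replicate(length(des$labels), random_diagram(sample(0:2, 1)),
                   simplify = FALSE)
  a <- vine_permutation_test(dgs, des, n_perm = 199, seed = 4)
  b <- vine_permutation_test(dgs, des, n_perm = 199, seed = 4)
  expect_identical(a$null_statistics, b$null_statistics)  # bit reproducible
  expect_identical(a$p.value, b$p.value)

  swapped <- vine_permutation_test(dgs, des, n_perm = 199, seed = 4,
                                   conditions = c("retrieval", "encoding"))
  expect_equal(swapped$statistic, a$statistic)
  expect_equal(swapped$p.value, a$p.value)

  expect_error(vine_permutation_test(dgs, des, n_perm = 10), ">= 99")
  expect_error(vine_permutation_test(dgs[1:3], des, n_perm = 99),
               "does not match")
  # p-value respects the plus-one estimator bounds
  expect_gte(a$p.value, 1 / 200)
  expect_lte(a$p.value, 1)
})

test_that("designs parse from long and compact files", {
  f <- file.path(tempdir(), "des.csv")
  on.exit(unlink(f))
  writeLines(c("t,condition", "0,a", "1,a", "2,b", "3,b"), f)
  d1 <- read_design(f)
  expect_equal(d1$labels, c("a", "a", "b", "b"))
  expect_equal(nrow(d1$blocks), 2L)

  writeLines(c("condition,length", "a,2", "b,2", "a,2"), f)
  d2 <- read_design(f)
  expect_equal(length(d2$labels), 6L)
  expect_equal(d2$blocks$condition, c("a", "b", "a"))
  # blocks partition the index range contiguously
  expect_equal(d2$blocks$start, c(1L, 3L, 5L))
  expect_equal(d2$blocks$end, c(2L, 4L, 6L))
})
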
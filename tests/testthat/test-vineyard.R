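test_that("hausdorff3 evaluates the max-min formula on spatial coordinates", {
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(hausdorff3(A, A), 0)
  expect_equal(hausdorff3(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  expect_equal(hausdorff3(A, rbind(c(0, 0, 0))), 10)  # asymmetric directed parts
  expect_error(hausdorff3(A, matrix(numeric(), 0, 3)), "non-empty")
  # the amplitude (4th) column is ignored
  expect_equal(hausdorff3(cbind(A, c(0, 1000)), cbind(A, c(500, 0))), 0)
})

test_that("hausdorff3 is a metric on finite point sets", {
  set.seed(31)
  for (k in 1:30) {
    A <- matrix(runif(9, 0, 5), 3)
    B <- matrix(runif(12, 0, 5), 4)
    C <- matrix(runif(6, 0, 5), 2)
    expect_equal(hausdorff3(A, B), hausdorff3(B, A))
    expect_gte(hausdorff3(A, B) + hausdorff3(B, C) - hausdorff3(A, C), -1e-12)
    expect_equal(hausdorff3(A, A), 0)
    expect_gt(hausdorff3(A, B), 0)  # a.s. distinct random sets
  }
})

test_that("vineyard edges link consecutive loops with clamp shading", {
  s <- moving_ring_series(TT = 1)
  static <- fmri_series(rep(list(get_cloud(s, 1)), 3))
  static$t <- 0:2
  dgs <- diagrams_over_time(static, r_max = 12)
  vy <- build_vineyard(dgs, d_ref = 4)
  loops <- vapply(dgs, function(d) sum(d$features$dim == 1), integer(1))
  expect_true(all(loops >= 1))
  # identical diagrams with identical representatives: distance 0, shade 1
  expect_equal(nrow(vy$edges), sum(loops[-1] * loops[-3]))
  self <- vy$edges[vy$edges$from_id == vy$edges$to_id, ]
  expect_true(all(self$distance == 0 & self$shade == 1))
  expect_true(all(vy$edges$shade >= 0 & vy$edges$shade <= 1))
})

test_that("a drifting loop produces a chain of shade 1 - d/d_ref", {
  # an embedded amplitude ring carries two loop classes (the elevated ring
  # and the hole it punches in the surrounding lattice); track the dominant
  # one, which drifts 1 stereotactic unit per time index
  s <- moving_ring_series(TT = 3, step = 1)
  dgs <- diagrams_over_time(s, r_max = 12, persistence_floor = 0.8)
  vy <- build_vineyard(dgs, d_ref = 10)
  dom <- vapply(dgs, function(d) {
    f <- d$features[d$features$dim == 1, ]
    f$feature_id[which.max(f$persistence)]
  }, integer(1))
  chain <- vy$edges[(vy$edges$t_from == 0 & vy$edges$from_id == dom[1] &
                       vy$edges$to_id == dom[2]) |
                    (vy$edges$t_from == 1 & vy$edges$from_id == dom[2] &
                       vy$edges$to_id == dom[3]), ]
  expect_equal(nrow(chain), 2L)
  expect_equal(chain$distance, c(1, 1))
  expect_equal(chain$shade, c(0.9, 0.9))

  # representatives farther apart than d_ref get shade 0 (and prune drops them)
  vy0 <- build_vineyard(dgs, d_ref = 0.5)
  expect_true(all(vy0$edges$shade == 0))
  expect_equal(nrow(build_vineyard(dgs, d_ref = 0.5, prune = TRUE)$edges), 0L)
})

test_that("vine extraction is monotone and respects region and floor", {
  s <- moving_ring_series(TT = 3, step = 0)
  dgs <- diagrams_over_time(s, r_max = 12)
  vy <- build_vineyard(dgs)
  everything <- mask_box(c(-99, 99), c(-99, 99), c(-99, 99))

  all_sel <- extract_vine(vy, everything, min_persistence = 0)
  n_dim1 <- vapply(dgs, function(d) sum(d$features$dim == 1), integer(1))
  expect_equal(vapply(all_sel$diagrams, function(d) nrow(d$features), integer(1)),
               n_dim1)

  none <- extract_vine(vy, everything, min_persistence = Inf)
  expect_true(all(vapply(none$diagrams, function(d) nrow(d$features) == 0,
                         logical(1))))

  # monotone filtering: features kept at floor p are kept at any p' <= p
  hi <- extract_vine(vy, everything, min_persistence = 1.2)
  lo <- extract_vine(vy, everything, min_persistence = 0.4)
  for (i in seq_along(hi$diagrams))
    expect_true(all(hi$diagrams[[i]]$features$feature_id %in%
                      lo$diagrams[[i]]$features$feature_id))

  # a region away from the loop empties the selection
  far <- extract_vine(vy, mask_box(c(50, 60), c(50, 60), c(-1, 1)),
                      min_persistence = 0)
  expect_true(all(vapply(far$diagrams, function(d) nrow(d$features) == 0,
                         logical(1))))
})

test_that("rank_vines chains stable loops and separates disjoint ones", {
  # one embedded ring = two stable loop classes (ring + lattice hole), each
  # chained across every time index
  one <- moving_ring_series(TT = 4, step = 0)
  vy1 <- build_vineyard(diagrams_over_time(one, r_max = 12,
                                           persistence_floor = 0.8))
  cand1 <- rank_vines(vy1)
  expect_true(all(cand1$length == 4L))
  expect_true(all(cand1$t_start == 0L & cand1$t_end == 3L))
  reg <- candidate_region(cand1)
  expect_true(inherits(reg, "mask_region"))
  # the top chain's box surrounds the planted ring center (3, 3)
  expect_true(fmrivine:::mask_membership(reg, matrix(c(3, 3, 0), 1)))

  two <- two_ring_series(TT = 3)
  vy2 <- build_vineyard(diagrams_over_time(two, r_max = 12,
                                           persistence_floor = 0.8))
  cand2 <- rank_vines(vy2)
  expect_true(all(cand2$length == 3L))
  # the two top-scoring chains sit on the two disjoint planted rings
  top2 <- cand2[1:2, ]
  expect_true(max(top2$xmin) > min(top2$xmax))  # disjoint boxes in x

  # a high floor on pure noise yields no candidates
  noisy <- random_series(n_side = 4, TT = 3, seed = 3, sd = 0.1)
  vyn <- build_vineyard(diagrams_over_time(normalize_amplitudes(noisy),
                                           r_max = 12,
                                           persistence_floor = 50))
  expect_equal(nrow(rank_vines(vyn)), 0L)
})

test_that("vineyard JSON export is self-describing", {
  s <- moving_ring_series(TT = 2)
  vy <- build_vineyard(diagrams_over_time(s, r_max = 12,
                                          persistence_floor = 0.8))
  f <- file.path(tempdir(), "vy.json")
  on.exit(unlink(f))
  write_vineyard_json(vy, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$format, "fmrivine-vineyard-1")
  expect_equal(back$d_ref, 4)
  expect_equal(nrow(as.data.frame(back$edges)), nrow(vy$edges))
})
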
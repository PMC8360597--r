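test_that("hyperspace embedding is the identity on coordinates plus amplitude", {
  cl <- time_point_cloud(rbind(c(1, 2, 3), c(0, 0, 0), c(3, 0, 0)),
                         c(4.5, 0, 4), t = 0)
  h <- embed_hyperspace(cl)
  expect_equal(dim(h), c(3L, 4L))
  expect_equal(unname(h[1, ]), c(1, 2, 3, 4.5))
  # Euclidean metric in R^4: (0,0,0,0) to (3,0,0,4) is 5
  expect_equal(as.numeric(dist(h[2:3, ])), 5)
})

test_that("filtration follows the radius convention and the truncation cut", {
  two <- build_rips(rbind(0, 1), r_max = 12)
  expect_equal(nrow(two$simplices[[1]]$vertices), 2L)
  expect_equal(two$simplices[[2]]$radius, 0.5)  # balls touch at half distance

  far <- build_rips(rbind(0, 30), r_max = 12)
  expect_equal(nrow(far$simplices[[2]]$vertices), 0L)

  sq <- build_rips(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), r_max = 2)
  expect_equal(sq$simplices[[2]]$radius,
               c(rep(0.5, 4), rep(sqrt(2) / 2, 2)))
  # deterministic order: radius, then lexicographic vertex tuple
  expect_equal(sq$simplices[[2]]$vertices[1:2, 2], c(2L, 3L))

  expect_error(build_rips(matrix(runif(60), 20), point_cap = 10), "cap")
  expect_error(build_rips(rbind(0, 1), r_max = -1), "positive")
})

test_that("unit square yields the single loop class at (0.5, sqrt(2)/2)", {
  d <- rips_persistence(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), r_max = 2)
  f1 <- d$features[d$features$dim == 1, ]
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$birth, 0.5)
  expect_equal(f1$death, sqrt(2) / 2)  # sqrt(2) x birth, not 2 x birth
  rep_edges <- representative(d, f1$feature_id, "simplices")
  expect_equal(nrow(rep_edges), 4L)  # the four square sides
})

test_that("degenerate clouds produce only the expected component classes", {
  one <- rips_persistence(rbind(c(0, 0, 0)), r_max = 5)
  expect_equal(nrow(one$features), 1L)
  expect_true(one$features$truncated)
  expect_equal(one$features$birth, 0)

  # isolated points beyond the truncation: n truncated H0, no H1
  iso <- rips_persistence(rbind(0, 100, 200, 300), r_max = 12)
  expect_equal(sum(iso$features$dim == 0), 4L)
  expect_true(all(iso$features$truncated))
  expect_equal(sum(iso$features$dim == 1), 0L)
})

test_that("engine matches the rank-based oracle on random small clouds", {
  set.seed(7)
  for (k in 1:40) {
    n <- sample(4:10, 1)
    pts <- matrix(runif(n * sample(2:4, 1), 0, 3), n)
    rmax <- runif(1, 0.5, 3)
    eng <- rips_persistence(pts, r_max = rmax, max_dim = 2)
    orc <- rips_persistence_bruteforce(pts, r_max = rmax, max_dim = 2)
    expect_identical(engine_key(eng), oracle_key(orc))
  }
  # H0 class count at radius 0+ equals the point count
  pts <- matrix(runif(24), 8)
  d <- rips_persistence(pts, r_max = 10)
  expect_equal(sum(d$features$dim == 0 & d$features$birth == 0), 8L)
})

test_that("loop representatives are closed cycles within their radius budget", {
  set.seed(21)
  checked <- 0L
  for (k in 1:25) {
    pts <- matrix(runif(27, 0, 2), 9)
    d <- rips_persistence(pts, r_max = 3)
    f1 <- d$features[d$features$dim == 1, ]
    for (i in seq_len(nrow(f1))) {
      edges <- representative(d, f1$feature_id[i], "simplices")
      # closed cycle: every vertex has even degree in the edge set
      expect_true(all(table(as.integer(edges)) %% 2 == 0))
      # all cycle edges enter no later than the class's birth (the youngest
      # edge of the cycle is the birth edge), hence well before death
      radii <- apply(edges, 1, function(e)
        0.5 * sqrt(sum((pts[e[1], ] - pts[e[2], ])^2)))
      expect_lt(max(radii), f1$birth[i] + 1e-12)
      expect_equal(max(radii), f1$birth[i])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)  # the loop cases actually occurred
})

test_that("raising the truncation radius only completes the diagram", {
  set.seed(13)
  pts <- matrix(runif(30, 0, 2), 10)
  lo <- rips_persistence(pts, r_max = 0.8, max_dim = 2)$features
  hi <- rips_persistence(pts, r_max = 2.5, max_dim = 2)$features
  fin <- lo[!lo$truncated, c("dim", "birth", "death")]
  hifin <- hi[!hi$truncated, c("dim", "birth", "death")]
  key <- function(f) paste(f$dim, signif(f$birth, 12), signif(f$death, 12))
  expect_true(all(key(fin) %in% key(hifin)))
})

test_that("birth and death radii are exactly equivariant under scaling", {
  set.seed(5)
  pts <- matrix(runif(32, 0, 2), 8)
  base <- rips_persistence(pts, r_max = 3, max_dim = 2)$features
  for (c in c(0.1, 7)) {
    scaled <- rips_persistence(pts * c, r_max = 3 * c, max_dim = 2)$features
    expect_equal(scaled$birth, base$birth * c, tolerance = 1e-9)
    expect_equal(scaled$death, base$death * c, tolerance = 1e-9)
  }
})

test_that("small perturbations move matched pairs by at most twice the radius", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(3, 3))
  eps <- 0.01
  set.seed(17)
  pert <- sq + matrix(runif(length(sq), -eps, eps), nrow(sq))
  a <- rips_persistence(sq, r_max = 5)$features
  b <- rips_persistence(pert, r_max = 5)$features
  for (dd in 0:1) {
    fa <- a[a$dim == dd & !a$truncated, ]
    fb <- b[b$dim == dd & !b$truncated, ]
    expect_equal(nrow(fa), nrow(fb))
    fa <- fa[order(fa$birth, fa$death), ]
    fb <- fb[order(fb$birth, fb$death), ]
    expect_true(all(abs(fa$birth - fb$birth) <= 2 * eps + 1e-12))
    expect_true(all(abs(fa$death - fb$death) <= 2 * eps + 1e-12))
  }
})

test_that("diagram stacks are deterministic and honor the persistence floor", {
  s <- random_series(n_side = 3, TT = 3, seed = 1, sd = 0)  # constant series
  dgs <- diagrams_over_time(s, r_max = 2)
  expect_length(dgs, 3L)
  expect_equal(dgs[[1]]$features, dgs[[2]]$features)
  expect_equal(dgs[[2]]$features, dgs[[3]]$features)

  empty <- diagrams_over_time(s, r_max = 2, persistence_floor = Inf)
  expect_true(all(vapply(empty, function(d) nrow(d$features) == 0, logical(1))))
})

test_that("the ring volume carries one dominant loop in hyperspace", {
  rv <- ring_volume()  # 9 x 9 x 3, low ring around high cluster
  d <- rips_persistence(embed_hyperspace(rv), r_max = 3)
  f0 <- d$features[d$features$dim == 0, ]
  expect_gte(sum(f0$persistence >= 10 / 4), 2L)  # two components, scale h/4

  f1 <- d$features[d$features$dim == 1, ]
  f1 <- f1[order(-f1$persistence), ]
  expect_gte(f1$persistence[1], 2 * f1$persistence[2])  # dominance
  centroid <- colMeans(representative(d, f1$feature_id[1], "vertices"))
  expect_lt(sqrt(sum((centroid[1:2] - c(4, 4))^2)), 1)  # at the ring center

  # a flat lattice (high = low) has only the birth-0.5 square classes
  flat <- ring_volume(high = 0)
  df <- rips_persistence(embed_hyperspace(flat), r_max = 1)
  ff <- df$features[df$features$dim == 1, ]
  expect_true(all(abs(ff$birth - 0.5) < 1e-9))
})
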
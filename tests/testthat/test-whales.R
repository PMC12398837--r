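test_that("weighted covariance matches hand computations", {
  # two atoms, equal |charge|: only the xx entry survives, value d^2/2
  two <- molecule3d("two", c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
                    c(0.3, -0.3))
  S <- weighted_covariance(two, 1)
  expect_equal(S, rbind(c(2, 0, 0), c(0, 0, 0), c(0, 0, 0)))

  # coincident points give the zero matrix
  co <- molecule3d("co", c("C", "C"), rbind(c(1, 2, 3), c(1, 2, 3)),
                   c(0.2, 0.1))
  expect_equal(weighted_covariance(co, 1), matrix(0, 3, 3))

  # the self term contributes nothing: charge of the center is irrelevant
  two_b <- molecule3d("two_b", c("C", "C"), two$coords, c(9, -0.3))
  expect_equal(weighted_covariance(two_b, 1)[1, 1],
               4 * 0.3 / (9 + 0.3))
})

test_that("4-atom toy matches the brute-force oracle through the pipeline", {
  mol <- toy_tetrahedron()
  o <- oracle_whales_indices(mol$coords, mol$charges)
  for (j in 1:4) {
    S <- weighted_covariance(mol, j)
    w <- abs(mol$charges)
    S_naive <- matrix(0, 3, 3)
    for (i in 1:4) {
      d <- mol$coords[i, ] - mol$coords[j, ]
      S_naive <- S_naive + w[i] * (d %o% d)
    }
    expect_equal(S, S_naive / sum(w), tolerance = 1e-12)
  }
  acm <- acm_matrix(mol)
  expect_equal(unclass(acm), o$acm, tolerance = 1e-10, ignore_attr = TRUE)
  idx <- atomic_indices(acm)
  expect_equal(idx$isolation, o$isolation, tolerance = 1e-12)
  expect_equal(idx$remoteness, o$remoteness, tolerance = 1e-12)
  expect_equal(idx$ir, o$ir, tolerance = 1e-12)
})

test_that("all-zero charges raise a degenerate-weights error", {
  mol <- molecule3d("zq", c("C", "C", "C"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    c(0, 0, 0))
  expect_error(weighted_covariance(mol, 1),
               class = "whalescreen_degenerate_weights")
  expect_error(whales_descriptor(mol),
               class = "whalescreen_degenerate_weights")
})

test_that("ACM matrix has a zero diagonal and nonnegative finite entries", {
  for (seed in 1:5) {
    mol <- make_cloud(8, seed)
    acm <- acm_matrix(mol)
    expect_identical(diag(unclass(acm)), rep(0, 8))
    expect_true(all(is.finite(acm)) && all(acm >= 0))
  }
})

test_that("isolation never exceeds remoteness (IR <= 1)", {
  for (seed in 1:10) {
    idx <- atomic_indices(acm_matrix(make_cloud(sample(3:20, 1), seed)))
    expect_true(all(idx$ir > 0 & idx$ir <= 1 + 1e-12))
    expect_true(all(idx$isolation > 0 & idx$remoteness > 0))
  }
})

test_that("equilateral geometry with equal charges gives IR = 1 everywhere", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  mol <- molecule3d("equi", c("C", "C", "C"), coords, c(0.2, 0.2, 0.2))
  idx <- atomic_indices(acm_matrix(mol))
  expect_equal(idx$ir, rep(1, 3), tolerance = 1e-10)
})

test_that("pipeline agrees with the naive oracle on random point clouds", {
  for (seed in 1:12) {
    n <- 3 + (seed * 7) %% 25
    mol <- make_cloud(n, seed)
    o <- oracle_whales_indices(mol$coords, mol$charges)
    idx <- atomic_indices(acm_matrix(mol))
    expect_lt(max(abs(idx$isolation - o$isolation),
                  abs(idx$remoteness - o$remoteness),
                  abs(idx$ir - o$ir)), 1e-10)
  }
})

test_that("descriptor has the 33-value three-block percentile layout", {
  mol <- make_cloud(15, 42)
  v <- whales_descriptor(mol)
  expect_length(v, 33)
  expect_identical(names(v), whalescreen:::whales_block_names())
  for (b in 0:2) {
    block <- v[b * 11 + 1:11]
    expect_true(all(diff(block) >= 0))
  }
  idx <- atomic_indices(acm_matrix(mol))
  expect_equal(unname(v[1]), min(idx$isolation))
  expect_equal(unname(v[11]), max(idx$isolation))
  expect_equal(unname(v[23]), min(idx$ir))
  expect_equal(unname(v[33]), max(idx$ir))
  # repeated evaluation is bitwise identical
  expect_identical(as.numeric(v), as.numeric(whales_descriptor(mol)))
})

test_that("descriptor is invariant under rigid motions", {
  for (seed in 1:8) {
    mol <- make_cloud(12, seed)
    moved <- rigid_transform(mol, random_rotation(seed + 100),
                             c(5, -3, 2) * seed)
    expect_equal(as.numeric(whales_descriptor(moved)),
                 as.numeric(whales_descriptor(mol)), tolerance = 1e-8)
  }
})

test_that("descriptor is invariant under uniform charge scaling", {
  mol <- make_cloud(10, 9)
  v <- as.numeric(whales_descriptor(mol))
  scaled2 <- molecule3d(mol$id, mol$elements, mol$coords, mol$charges * 2)
  expect_identical(as.numeric(whales_descriptor(scaled2)), v)
  scaled_odd <- molecule3d(mol$id, mol$elements, mol$coords,
                           mol$charges * 1.7)
  expect_equal(as.numeric(whales_descriptor(scaled_odd)), v,
               tolerance = 1e-12)
})

test_that("descriptor is invariant under atom relabeling", {
  for (seed in 1:5) {
    mol <- make_cloud(11, seed)
    perm <- sample(11)
    permuted <- molecule3d(mol$id, mol$elements[perm],
                           mol$coords[perm, ], mol$charges[perm])
    expect_equal(as.numeric(whales_descriptor(permuted)),
                 as.numeric(whales_descriptor(mol)), tolerance = 1e-10)
  }
})

test_that("descriptor CSV round-trips", {
  mols <- lapply(1:3, function(s) make_cloud(8, s, id = paste0("m", s)))
  d <- whales_descriptors(mols)
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(d, path)
  expect_equal(read_descriptors(path), d, tolerance = 1e-12)
})
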
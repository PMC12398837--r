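rand_desc <- function(seed) {
  set.seed(seed)
  stats::runif(33)
}

test_that("similarity distance has closed-form values and symmetry", {
  x <- rand_desc(1)
  expect_identical(similarity_distance(x, x), 0)
  e1 <- c(1, rep(0, 32)); e2 <- c(0, 1, rep(0, 31))
  expect_equal(similarity_distance(e1, e2), sqrt(2))
  y <- rand_desc(2)
  expect_identical(similarity_distance(x, y), similarity_distance(y, x))
  expect_error(similarity_distance(x[1:10], y),
               class = "whalescreen_contract_error")
})

test_that("similarity distance satisfies the metric axioms on random triples", {
  for (seed in 1:20) {
    x <- rand_desc(seed); y <- rand_desc(seed + 50); z <- rand_desc(seed + 100)
    dxy <- similarity_distance(x, y)
    dyz <- similarity_distance(y, z)
    dxz <- similarity_distance(x, z)
    expect_gte(dxy, 0)
    expect_lte(dxz, dxy + dyz + 1e-12)   # triangle inequality
    expect_equal(dxy, similarity_distance(y, x))
  }
  expect_gt(similarity_distance(rand_desc(1), rand_desc(2)), 0)
})

test_that("a template present in the library ranks first with distance zero", {
  lib <- t(vapply(1:30, rand_desc, numeric(33)))
  rownames(lib) <- sprintf("lib%02d", 1:30)
  tmpl <- lib[7, , drop = FALSE]
  rownames(tmpl) <- "lib07"
  expect_message(hits <- rank_library(tmpl, lib, top_k = 5), "lib07")
  expect_identical(hits$molecule_id[1], "lib07")
  expect_identical(hits$aggregate_distance[1], 0)
  expect_identical(hits$rank, 1:5)
})

test_that("top_k clamps to the library size and ranks have no gaps", {
  lib <- t(vapply(1:4, rand_desc, numeric(33)))
  rownames(lib) <- sprintf("m%d", 1:4)
  tmpl <- matrix(rand_desc(99), 1)
  hits <- rank_library(tmpl, lib, top_k = 100)
  expect_equal(nrow(hits), 4)
  expect_identical(hits$rank, 1:4)
  expect_true(!is.unsorted(hits$aggregate_distance))
  expect_error(rank_library(tmpl, lib, top_k = 0),
               class = "whalescreen_contract_error")
})

test_that("ranking is independent of library order with id tie-breaks", {
  base <- rand_desc(5)
  lib <- rbind(base + 0.1, base + 0.1, base + 0.3)  # two exact ties
  rownames(lib) <- c("bbb", "aaa", "ccc")
  tmpl <- matrix(base, 1, dimnames = list("q", NULL))
  h1 <- rank_library(tmpl, lib, top_k = 3)
  h2 <- rank_library(tmpl, lib[c(3, 1, 2), ], top_k = 3)
  expect_identical(h1$molecule_id, h2$molecule_id)
  expect_identical(h1$molecule_id[1:2], c("aaa", "bbb"))
})

test_that("min and mean aggregation follow their definitions", {
  lib <- t(vapply(1:6, rand_desc, numeric(33)))
  rownames(lib) <- sprintf("m%d", 1:6)
  tmpls <- t(vapply(7:9, rand_desc, numeric(33)))
  rownames(tmpls) <- sprintf("t%d", 1:3)
  hits <- rank_library(tmpls, lib, top_k = 6, aggregate = "min")
  for (k in seq_len(6)) {
    per <- vapply(1:3, function(t) {
      similarity_distance(lib[hits$molecule_id[k], ], tmpls[t, ])
    }, numeric(1))
    expect_equal(hits$aggregate_distance[k], min(per), tolerance = 1e-12)
    expect_equal(unlist(hits[k, paste0("dist_t", 1:3)], use.names = FALSE),
                 per, tolerance = 1e-12)
  }
  hits_mean <- rank_library(tmpls, lib, top_k = 6, aggregate = "mean")
  per1 <- vapply(1:3, function(t) {
    similarity_distance(lib[hits_mean$molecule_id[1], ], tmpls[t, ])
  }, numeric(1))
  expect_equal(hits_mean$aggregate_distance[1], mean(per1), tolerance = 1e-12)
})

test_that("adding a strictly worse molecule never reorders existing hits", {
  lib <- t(vapply(1:10, rand_desc, numeric(33)))
  rownames(lib) <- sprintf("m%02d", 1:10)
  tmpl <- matrix(rand_desc(42), 1, dimnames = list("q", NULL))
  before <- rank_library(tmpl, lib, top_k = 10)
  worse <- matrix(rand_desc(42) + 10, 1, dimnames = list("zz_worse", NULL))
  after <- rank_library(tmpl, rbind(lib, worse), top_k = 11)
  expect_identical(after$molecule_id[1:10], before$molecule_id)
  expect_identical(after$molecule_id[11], "zz_worse")
})

test_that("screening reports round-trip through CSV", {
  lib <- t(vapply(1:30, rand_desc, numeric(33)))
  rownames(lib) <- sprintf("m%02d", 1:30)
  tmpls <- t(vapply(31:32, rand_desc, numeric(33)))
  rownames(tmpls) <- c("q1", "q2")
  hits <- rank_library(tmpls, lib, top_k = 27)
  expect_equal(nrow(hits), 27)
  path <- withr::local_tempfile(fileext = ".csv")
  screening_report(hits, path)
  back <- read_screening_report(path)
  expect_identical(back$molecule_id, hits$molecule_id)
  expect_identical(back$rank, hits$rank)
  expect_equal(back$aggregate_distance, hits$aggregate_distance,
               tolerance = 1e-12)
  expect_error(screening_report(hits[0, ], path),
               class = "whalescreen_contract_error")
})
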
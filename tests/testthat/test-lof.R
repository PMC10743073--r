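# Local Outlier Factor: definitional checks against hand enumeration and an
# independent brute-force oracle, symmetry properties, ranking helpers.

test_that("k-distance matches direct definition and rejects invalid k", {
  two <- feature_dataset(rbind(c(0, 0), c(3, 4)))
  expect_equal(k_distance(two, "p1", 1), 5)
  expect_error(k_distance(two, "p1", 2), "k must be")

  ds <- make_gaussian_dataset(6L, seed = 17L)
  D <- oracle_dist(ds$X)
  for (q in seq_len(6L)) {
    expect_equal(k_distance(ds, paste0("p", q), 3), oracle_kdist(D, q, 3))
  }
})

test_that("reachability distance follows max(d, k-distance) including its asymmetry", {
  line <- feature_dataset(matrix(c(0, 1, 10), ncol = 1),
                          ids = c("a", "b", "c"))
  # hand-enumerated table at k = 1: kdist(a)=1, kdist(b)=1, kdist(c)=9
  expect_equal(reachability_distance(line, "c", "b", 1), 9)  # far from b
  expect_equal(reachability_distance(line, "b", "c", 1), 9)  # floored by kdist(c)
  expect_equal(reachability_distance(line, "b", "a", 1), 1)
  expect_equal(reachability_distance(line, "a", "b", 1), 1)
  expect_error(reachability_distance(line, "a", "a", 1), "p != q")

  ds <- make_gaussian_dataset(7L, seed = 23L)
  D <- oracle_dist(ds$X)
  for (p in 1:7) for (q in setdiff(1:7, p)) {
    expect_equal(
      reachability_distance(ds, paste0("p", p), paste0("p", q), 3),
      oracle_rd(D, p, q, 3))
  }
})

test_that("lrd is the inverse mean reachability distance, duplicate-safe", {
  s <- 1.7
  tri <- feature_dataset(s * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  for (p in c("p1", "p2", "p3")) {
    expect_equal(lrd(tri, p, 1), 1 / s, tolerance = 1e-12)
  }
  dup <- feature_dataset(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_true(all(is.finite(lof_all(dup, 1))))
  expect_lte(lrd(dup, "p1", 1), 1e12)
})

test_that("LOF agrees with the brute-force oracle on exhaustive small instances", {
  for (n in 3:8) {
    for (seed in 1:3) {
      for (ds in list(make_grid_dataset(n, seed = 100 * n + seed),
                      make_gaussian_dataset(n, seed = 200 * n + seed))) {
        for (k in seq_len(n - 1L)) {
          expect_equal(unname(lof_all(ds, k)), oracle_lof_all(ds$X, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("LOF is 1 on point sets with a transitive symmetry group", {
  for (n in c(3, 5, 8, 12)) {
    poly <- make_polygon(n)
    for (k in seq_len(n - 1L)) {
      expect_equal(unname(lof_all(poly, k)), rep(1, n), tolerance = 1e-12)
    }
  }
  # 3-cube vertices
  cube <- feature_dataset(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  for (k in c(1, 3, 7)) {
    expect_equal(unname(lof_all(cube, k)), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("a far point scores a clearly elevated LOF", {
  ds <- with_local_seed(31L, {
    X <- matrix(rnorm(100, sd = 0.5), 50, 2)
    feature_dataset(rbind(X, c(30, 30)))
  })
  expect_gt(lof(ds, "p51", 5), 2)
  expect_equal(lof(ds, "p51", 5), oracle_lof(oracle_dist(ds$X), 51L, 5L),
               tolerance = 1e-12)
})

test_that("lof_curve records the sweep with its maximum and argmax", {
  poly <- make_polygon(9)
  flat <- lof_curve(poly, "p1", 2, 8)
  expect_equal(flat$lof_values, rep(1, 7), tolerance = 1e-12)
  expect_equal(flat$k_values, 2:8)

  single <- lof_curve(poly, "p1", 3, 3)
  expect_length(single$lof_values, 1L)
  expect_equal(single$max_lof, single$lof_values[1L])

  ds <- make_gaussian_dataset(20L, seed = 41L)
  curve <- lof_curve(ds, "p7", 2, 19)
  oracle_vals <- vapply(2:19, function(k) oracle_lof(oracle_dist(ds$X), 7L, k),
                        numeric(1))
  expect_equal(curve$lof_values, oracle_vals, tolerance = 1e-12)
  expect_equal(curve$max_lof, max(oracle_vals), tolerance = 1e-12)
  expect_equal(curve$argmax_k, (2:19)[which.max(oracle_vals)])
  expect_error(lof_curve(ds, "p7", 0, 5), "invalid k range")
})

test_that("reference curves hold the pointwise median and minimum", {
  poly <- make_polygon(10)
  rc <- reference_curves(poly, 2, 9)
  expect_equal(rc$median_lof, rep(1, 8), tolerance = 1e-12)
  expect_equal(rc$min_lof, rep(1, 8), tolerance = 1e-12)

  ds <- make_gaussian_dataset(30L, seed = 53L)
  rc <- reference_curves(ds, 2, 10)
  for (j in seq_along(rc$k_values)) {
    v <- oracle_lof_all(ds$X, rc$k_values[j])
    expect_equal(rc$median_lof[j], stats::median(v), tolerance = 1e-12)
    expect_equal(rc$min_lof[j], min(v), tolerance = 1e-12)
  }
  expect_true(all(rc$min_lof <= rc$median_lof))
})

test_that("percentile ranks follow the mid-rank convention", {
  expect_equal(percentile_rank(-10, 1:5), 0)
  expect_equal(percentile_rank(7, c(7)), 50)
  expect_equal(percentile_rank(3, 1:5), 50)
  expect_equal(percentile_rank(100, 1:5), 100)
  pop <- with_local_seed(61L, runif(37))
  expect_equal(percentile_rank(min(pop), pop) + percentile_rank(max(pop), pop),
               100)
  expect_error(percentile_rank(1, numeric(0)), "non-empty")
})

test_that("histogram bins are half-open with a closed last bin", {
  expect_equal(histogram_counts(0.5, bin_edges = c(0, 1)), 1L,
               ignore_attr = TRUE)
  expect_equal(histogram_counts(c(0, 0.5, 1), bin_edges = c(0, 1, 2)),
               c(2L, 1L), ignore_attr = TRUE)
  expect_equal(histogram_counts(c(0, 1, 2), bin_edges = c(0, 1, 2)),
               c(1L, 2L), ignore_attr = TRUE)
  expect_error(histogram_counts(1, bin_edges = c(1, 1)), "strictly increasing")
  cloud <- make_feature_cloud(cloud_spec(seed = 5L))
  counts <- histogram_counts(cloud$X[, "dom"], bin_count = 25L)
  expect_equal(sum(counts), nrow(cloud$X))
})

test_that("z-score standardization is applied before distances", {
  X <- with_local_seed(71L, cbind(a = rnorm(40, 5, 10), b = rnorm(40, -2, 0.1)))
  ds <- feature_dataset(X, standardize = TRUE)
  expect_equal(unname(colMeans(ds$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ds$X, 2, stats::sd)), c(1, 1), tolerance = 1e-12)
})

test_that("feature TSVs round-trip through read_feature_tsv", {
  cloud <- make_feature_cloud(cloud_spec(seed = 9L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(cloud, path)
  back <- read_feature_tsv(path, features = c("ruf", "dom"))
  expect_equal(nrow(back$X), nrow(cloud$X))
  expect_equal(back$X, cloud$X, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true("planted_outlier" %in% names(back$labels))
})
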
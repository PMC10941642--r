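test_that("scheme grid enumerates exactly 97 unique recipes", {
  g <- enumerate_schemes()
  expect_length(g, 97)
  labels <- vapply(g, format, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  # composition of the grid
  expect_equal(sum(grepl("^ccmn", labels)), 49)
  expect_equal(sum(grepl("^none", labels)), 48)
  g_raw <- enumerate_schemes(include_raw = TRUE)
  expect_length(g_raw, 98)
  expect_equal(format(g_raw[[1]]), "raw")
})

test_that("VIP similarity: worked values, symmetry, errors", {
  x <- c(0.6, 0.8)
  expect_identical(vip_similarity(x, x), 1)
  expect_identical(vip_similarity(c(1, 0), c(0, 0)), 0)
  # normalized variant: x scaled to unit norm, distance to zero is 1
  expect_identical(vip_similarity(c(0.6, 0.8), c(0, 0),
                                  normalize = TRUE), 0)
  set.seed(4)
  a <- runif(8); b <- runif(8)
  expect_equal(vip_similarity(a, b), vip_similarity(b, a))
  expect_equal(vip_similarity(a, b, TRUE), vip_similarity(b, a, TRUE))
  expect_error(vip_similarity(1:3, 1:4), "length")
})

test_that("cluster_vips: forced topologies and the naive oracle", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  h <- cluster_vips(m)
  expect_equal(h$height[1], 0)           # identical rows merge first
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  m2 <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  h2 <- cluster_vips(m2)
  expect_equal(h2$height[1], 1)          # the two close rows first
  # complete-linkage heights match a brute-force agglomeration
  for (seed in 1:3) {
    set.seed(seed)
    m3 <- matrix(rnorm(24), 6, 4)
    expect_equal(cluster_vips(m3)$height, naive_complete_heights(m3),
                 tolerance = 1e-8)
  }
  expect_error(cluster_vips(m[1, , drop = FALSE]), "2 rows")
  m[1, 1] <- NA
  expect_error(cluster_vips(m), "missing")
})

test_that("benchmark on a noise-free pair: raw is a perfect match and argmax", {
  pair <- simulate_pair(sim_design(samples_per_group = c(8, 8),
                                   n_features = 8, n_dominant = 1,
                                   n_is = 1, sigma_e = 0,
                                   sigma_analyte = 0, seed = 21))
  expect_identical(split_standards(pair$area)$analytes$values,
                   pair$conc$values)
  bm <- run_benchmark(pair$area, pair$conc, compute_properties = FALSE)
  sim <- setNames(bm$similarity$similarity, bm$similarity$scheme)
  expect_identical(unname(sim["raw"]), 1)
  expect_equal(names(which.max(sim)), "raw")
})

test_that("benchmark bookkeeping: rows, skip policy, determinism", {
  pair <- simulate_pair(bench_design(5))
  bm <- run_benchmark(pair$area, pair$conc, compute_properties = FALSE)
  expect_equal(bm$config$n_schemes, 97)
  # every scheme is either evaluated or skipped with a reason
  expect_equal(nrow(bm$similarity) + nrow(bm$skipped), 98)
  expect_true(all(nzchar(bm$skipped$reason)))
  # VIP matrix has the reference first, then all evaluated schemes
  expect_equal(rownames(bm$vip_matrix)[1], "conc")
  expect_equal(nrow(bm$vip_matrix), nrow(bm$similarity) + 1)
  # deterministic: identical rerun
  bm2 <- run_benchmark(pair$area, pair$conc, compute_properties = FALSE)
  expect_identical(bm$similarity, bm2$similarity)
  expect_identical(bm$vip_matrix, bm2$vip_matrix)
  # zeros in the data force log schemes into the skip list
  area0 <- pair$area
  area0$values[1, 1] <- 0
  bm0 <- run_benchmark(area0, pair$conc, compute_properties = FALSE)
  expect_true(any(grepl("log2", bm0$skipped$scheme)))
  expect_false(any(grepl("+log2+", rownames(bm0$vip_matrix),
                         fixed = TRUE)))
})

test_that("benchmark validates shared keys", {
  pair <- simulate_pair(bench_design(1))
  conc_bad <- pair$conc
  conc_bad$feature_ids[1] <- "other"
  colnames(conc_bad$values)[1] <- "other"
  expect_error(run_benchmark(pair$area, conc_bad), "feature ids")
  conc_g <- pair$conc
  conc_g$group[1] <- "mystery"
  expect_error(run_benchmark(pair$area, conc_g), "group")
})

test_that("plain ccmn brings area VIPs closer to the reference than raw", {
  wins <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    pair <- simulate_pair(bench_design(seed))
    ref <- run_plsda(pair$conc)$vip
    raw <- run_plsda(split_standards(pair$area)$analytes)$vip
    cc <- run_plsda(normalize_ccmn(pair$area)$dataset)$vip
    wins <- wins + (vip_similarity(cc, ref) > vip_similarity(raw, ref))
  }
  expect_gte(wins / n_rep, 0.6)
})

test_that("property-profile PCA over schemes is produced", {
  pair <- simulate_pair(sim_design(samples_per_group = c(6, 6),
                                   n_features = 6, n_is = 1,
                                   n_qc = 4, seed = 2))
  bm <- suppressWarnings(run_benchmark(pair$area, pair$conc,
                                       compute_properties = TRUE))
  expect_s3_class(bm$profile_pca, "pca_result")
  expect_gte(nrow(bm$profile_pca$scores), 90)
  lam <- bm$config$glog_lambdas_used
  expect_true(all(grepl("glog", names(lam))))
  expect_true(all(unlist(lam) > 0))
})
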
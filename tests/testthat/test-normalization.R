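test_that("IS-ratio normalization: identity, arithmetic, scale invariance", {
  vals <- cbind(met_a = c(10, 8), met_b = c(6, 4), IS_1 = c(1, 1))
  d <- met_dataset(vals, group = c("g1", "g2"),
                   is_internal_standard = c(FALSE, FALSE, TRUE))
  out <- normalize_is_ratio(d)
  expect_equal(unname(out$values),
               unname(vals[, 1:2]))  # IS identically 1 -> identity
  expect_false(any(out$is_internal_standard))

  vals2 <- cbind(met_a = c(10, 10), IS_1 = c(2, 5))
  d2 <- met_dataset(vals2, group = c("g1", "g2"),
                    is_internal_standard = c(FALSE, TRUE))
  expect_equal(unname(normalize_is_ratio(d2)$values[, 1]), c(5, 2))

  # doubling a sample's analytes and IS leaves its normalized row alone
  vals3 <- vals2; vals3[2, ] <- 2 * vals3[2, ]
  d3 <- met_dataset(vals3, group = c("g1", "g2"),
                    is_internal_standard = c(FALSE, TRUE))
  expect_equal(normalize_is_ratio(d3)$values[2, ],
               normalize_is_ratio(d2)$values[2, ])

  vals4 <- cbind(met_a = c(1, 1), IS_1 = c(0, 2))
  d4 <- met_dataset(vals4, group = c("g1", "g2"),
                    is_internal_standard = c(FALSE, TRUE))
  expect_error(normalize_is_ratio(d4), "non-positive")
})

test_that("nomis: perfect fit and zero-covariance cases", {
  # analyte exactly equal to the IS: residual variance 0 after correction
  s <- c(2, 4, 8, 16, 3, 9)
  vals <- cbind(met_a = s, IS_1 = s)
  d <- met_dataset(vals, group = rep(c("g1", "g2"), 3),
                   is_internal_standard = c(FALSE, TRUE))
  out <- normalize_nomis(d)
  expect_equal(stats::var(log(out$dataset$values[, 1])), 0,
               tolerance = 1e-12)

  # centred log analyte orthogonal to centred log IS: output == input
  lx <- c(1, -2, 1)          # centred log analyte
  ls <- c(-1, 0, 1)          # centred log IS; crossprod(lx, ls) == 0
  vals2 <- cbind(met_a = exp(5 + lx), IS_1 = exp(3 + ls))
  d2 <- met_dataset(vals2, group = c("a", "b", "a"),
                    is_internal_standard = c(FALSE, TRUE))
  out2 <- normalize_nomis(d2)
  expect_equal(unname(out2$dataset$values[, 1]), unname(vals2[, 1]),
               tolerance = 1e-10)
})

test_that("ccmn with a constant IS applies zero correction", {
  d <- toy_dataset(n = 8, p = 4, n_is = 1, seed = 3)
  d$values[, 4] <- 42  # constant IS: no error signal
  out <- normalize_ccmn(d)
  expect_equal(out$dataset$values, d$values[, 1:3], tolerance = 1e-10)
})

test_that("ccmn argument validation", {
  d <- toy_dataset(n = 6, p = 4, n_is = 1)
  expect_error(normalize_ccmn(d, np = 2), "internal standards")
  d_bad <- d; d_bad$values[2, 1] <- -1
  err <- expect_error(normalize_ccmn(d_bad))
  expect_match(conditionMessage(err), "met_1")
  expect_match(conditionMessage(err), "s2")
})

test_that("single-IS ccmn equals removing the design-orthogonalized IS direction", {
  # independent closed-form oracle for q = 1, np = 1
  d <- toy_dataset(n = 10, p = 5, n_is = 1, seed = 9)
  out <- normalize_ccmn(d, np = 1)
  parts <- split_standards(d)
  Z <- log(parts$analytes$values)
  l <- log(parts$standards$values[, 1])
  lc <- l - mean(l)
  G <- stats::model.matrix(~ 0 + factor(d$group))
  r <- lc - G %*% solve(crossprod(G), crossprod(G, lc))
  Zc <- scale(Z, scale = FALSE)
  fitted <- r %*% (crossprod(r, Zc) / sum(r^2))
  oracle <- exp(sweep(Zc - fitted, 2, colMeans(Z), `+`))
  expect_equal(unname(out$dataset$values), unname(oracle),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("ccmn correction scores are orthogonal to the group design", {
  for (seed in 1:5) {
    pair <- simulate_pair(sim_design(samples_per_group = c(7, 5, 8),
                                     n_features = 8, n_is = 2,
                                     sigma_e = 0.4, seed = seed))
    m <- normalize_ccmn(pair$area, np = 2)$model
    G <- stats::model.matrix(~ 0 + factor(pair$area$group))
    expect_lt(max(abs(crossprod(G, m$scores))), 1e-8)
  }
})

test_that("without shared error, ccmn and nomis leave group means unchanged", {
  # analytes and IS independent, sigma_e = 0: corrections are noise-level
  pair <- simulate_pair(sim_design(samples_per_group = c(15, 15),
                                   n_features = 6, n_is = 1,
                                   sigma_e = 0, sigma_analyte = 0.2,
                                   seed = 4))
  raw <- split_standards(pair$area)$analytes
  grp <- factor(raw$group)
  gm <- function(v) apply(log(v), 2, function(x) tapply(x, grp, mean))
  for (out in list(normalize_ccmn(pair$area)$dataset,
                   normalize_nomis(pair$area)$dataset)) {
    expect_equal(gm(out$values), gm(raw$values), tolerance = 0.05)
  }
})

test_that("ccmn reduces per-group CVs under shared multiplicative error", {
  hits <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    pair <- simulate_pair(sim_design(samples_per_group = c(10, 10),
                                     n_features = 10, n_is = 1,
                                     sigma_e = 0.3, sigma_analyte = 0.1,
                                     seed = seed))
    raw <- split_standards(pair$area)$analytes
    cv <- function(d) {
      g <- factor(d$group)
      mean(apply(d$values, 2,
                 function(v) tapply(v, g, stats::sd) / tapply(v, g, mean)))
    }
    hits <- hits + (cv(normalize_ccmn(pair$area)$dataset) < cv(raw))
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("group signal leaking into the IS: ccmn keeps it, nomis removes it", {
  hits <- 0
  n_rep <- 10
  for (seed in seq_len(n_rep)) {
    pair <- simulate_pair(bench_design(seed, is_group_leak = 0.5))
    f_ccmn <- mean_group_f(normalize_ccmn(pair$area)$dataset)
    f_nomis <- mean_group_f(normalize_nomis(pair$area)$dataset)
    hits <- hits + (f_ccmn >= f_nomis)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("ccmn error scores recover the true shared error (np = 1)", {
  hits <- 0
  n_rep <- 15
  for (seed in seq_len(n_rep)) {
    pair <- simulate_pair(sim_design(samples_per_group = c(15, 15),
                                     n_features = 10, n_is = 1,
                                     sigma_e = 0.3, sigma_analyte = 0.2,
                                     seed = seed))
    m <- normalize_ccmn(pair$area, np = 1)$model
    hits <- hits +
      (abs(stats::cor(m$scores[, 1], pair$truth$log_e)) > 0.9)
  }
  expect_gte(hits / n_rep, 0.9)
})
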
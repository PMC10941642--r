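mkd <- function(vals, ...) {
  vals <- as.matrix(vals)
  met_dataset(vals, group = rep("g", nrow(vals)), ...)
}

test_that("transformations: worked element-wise values and domains", {
  d <- mkd(cbind(a = c(4, 0, 9)))
  expect_equal(unname(transform_features(d, "sqrt")$values[, 1]),
               c(2, 0, 3))
  expect_equal(unname(transform_features(mkd(cbind(a = c(-8, 27))),
                                         "cube")$values[, 1]), c(-2, 3))
  # glog with lambda = 0 equals the plain log on positive data
  d8 <- mkd(cbind(a = c(8, 2)))
  expect_equal(unname(transform_features(d8, "glog2",
                                         glog_lambda = 0)$values[, 1]),
               c(3, 1))
  expect_equal(transform_features(d8, "log10")$values,
               log10(d8$values), ignore_attr = TRUE)
  # domain violations name the method and the cell
  d0 <- mkd(cbind(a = c(1, 0)))
  expect_error(transform_features(d0, "log10"), "log10")
  expect_error(transform_features(d0, "log2"), "strictly positive")
  expect_error(transform_features(mkd(cbind(a = -1)), "sqrt"),
               "non-negative")
  # cube and glog accept zero and negatives
  dn <- mkd(cbind(a = c(-3, 0, 5)))
  expect_no_error(transform_features(dn, "cube"))
  expect_no_error(transform_features(dn, "glog10"))
})

test_that("glog lambda selection squares the smallest positive value", {
  lam <- select_glog_lambda(mkd(cbind(a = c(0.1, 5), b = c(3, 2))))
  expect_equal(lam$lambda, 0.01)
  expect_equal(lam$rule, "min_positive_squared")
  lam2 <- select_glog_lambda(mkd(cbind(a = c(1000, 2000))))
  expect_equal(lam2$lambda, 1e6)
  expect_error(select_glog_lambda(mkd(cbind(a = c(0, 0)))),
               "positive")
  # the chosen lambda is surfaced on the transformed dataset
  out <- transform_features(mkd(cbind(a = c(0.5, 2))), "glog2")
  expect_equal(attr(out, "glog_parameter")$lambda, 0.25)
})

test_that("glog is monotone and converges to the plain log", {
  x <- sort(rlnorm(50, 0, 2))
  d <- mkd(cbind(a = x))
  for (m in c("glog2", "glog10")) {
    y <- transform_features(d, m, glog_lambda = 1)$values[, 1]
    expect_true(all(diff(y) > 0))
    y0 <- transform_features(d, m, glog_lambda = 1e-12)$values[, 1]
    base <- if (m == "glog2") 2 else 10
    expect_equal(unname(y0), log(x, base), tolerance = 1e-6)
  }
})

test_that("monotone transforms preserve rank and compress spread", {
  set.seed(2)
  x <- rlnorm(20, 3, 1) + 1
  d <- mkd(cbind(a = x))
  for (m in TRANSFORM_METHODS) {
    y <- transform_features(d, m)$values[, 1]
    expect_equal(order(y), order(x), info = m)
    # for x2 > x1 > 1 the transformed gap is smaller
    o <- order(x)
    expect_true(all(diff(y[o]) < diff(x[o])), info = m)
  }
})

test_that("scalings: worked values", {
  d <- mkd(cbind(a = c(1, 2, 3)))
  expect_equal(unname(scale_features(d, "auto")$values[, 1]),
               c(-1, 0, 1))
  expect_equal(unname(scale_features(d, "vast")$values[, 1]),
               c(-2, 0, 2))
  d2 <- mkd(cbind(a = c(0, 2, 4)))
  expect_equal(unname(scale_features(d2, "pareto")$values[, 1]),
               c(-sqrt(2), 0, sqrt(2)))
  d3 <- mkd(cbind(a = c(1, 3)))
  expect_equal(unname(scale_features(d3, "level")$values[, 1]),
               c(-0.5, 0.5))
  expect_equal(unname(scale_features(d3, "range")$values[, 1]),
               c(-0.5, 0.5))
})

test_that("power scaling equals sqrt transform plus mean centring, exactly", {
  d <- toy_dataset(n = 7, p = 3, seed = 5)
  via_power <- scale_features(d, "power")$values
  sq <- transform_features(d, "sqrt")$values
  via_sqrt <- sweep(sq, 2, colMeans(sq))
  expect_identical(via_power, via_sqrt)
})

test_that("degenerate features are rejected by name", {
  d <- mkd(cbind(ok = c(1, 2, 3), flat = c(5, 5, 5)))
  for (m in c("auto", "pareto", "vast"))
    expect_error(scale_features(d, m), "flat")
  expect_error(scale_features(d, "range"), "zero range")
  dz <- mkd(cbind(z = c(-1, 1)))
  expect_error(scale_features(dz, "level"), "zero mean")
  expect_warning(scale_features(mkd(cbind(a = c(-1, -3))), "level"),
                 "negative")
  expect_error(scale_features(mkd(cbind(a = c(-1, 2))), "power"),
               "non-negative")
})

test_that("scaled features are centred; auto-scaled have unit variance", {
  d <- toy_dataset(n = 9, p = 5, seed = 8)
  for (m in c("auto", "level", "pareto", "range", "vast")) {
    out <- scale_features(d, m)$values
    expect_lt(max(abs(colMeans(out))), 1e-10)
  }
  expect_equal(unname(apply(scale_features(d, "auto")$values, 2,
                            stats::sd)), rep(1, 5), tolerance = 1e-10)
})

test_that("scheme ids serialize canonically", {
  expect_equal(format(scheme_id()), "raw")
  expect_equal(format(scheme_id("ccmn", "sqrt", "none")),
               "ccmn+sqrt+none")
  s <- parse_scheme("ccmn+sqrt+none")
  expect_equal(s$normalization, "ccmn")
  expect_equal(s$transformation, "sqrt")
  expect_equal(s$scaling, "none")
  expect_equal(parse_scheme("raw")$normalization, "none")
  expect_equal(parse_scheme("pareto")$scaling, "pareto")
  expect_error(parse_scheme("bogus"), "unknown")
})

test_that("apply_scheme composes stages in the fixed order", {
  pair <- simulate_pair(sim_design(samples_per_group = c(6, 6),
                                   n_features = 5, n_is = 1, seed = 12))
  d <- pair$area
  # raw is the identity
  expect_identical(apply_scheme(d, "raw")$values, d$values)
  # ccmn+sqrt+none == normalize_ccmn then sqrt
  a <- apply_scheme(d, "ccmn+sqrt+none")
  b <- transform_features(normalize_ccmn(d)$dataset, "sqrt")
  expect_equal(a$values, b$values)
  expect_equal(a$unit_tag, "processed:ccmn+sqrt+none")
  # none+sqrt+power == sqrt applied twice plus centring,
  # i.e. power scaling of the sqrt data
  r <- apply_scheme(d, "none+sqrt+power")
  sq <- transform_features(d, "sqrt")
  expect_equal(r$values, scale_features(sq, "power")$values)
  # errors are annotated with the failing stage
  dz <- d; dz$values[1, 1] <- 0
  expect_error(apply_scheme(dz, "none+log2+none"),
               "transformation stage")
  expect_error(apply_scheme(toy_dataset(n_is = 0), "ccmn+none+none"),
               "normalization stage")
})
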
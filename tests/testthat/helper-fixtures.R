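# Shared fixtures and independent oracles.

# Quick dataset builder: positive values, simple two-group layout.
toy_dataset <- function(n = 6, p = 4, groups = c("a", "b"), seed = 1,
                        n_is = 0, unit_tag = "area") {
  set.seed(seed)
  vals <- matrix(rlnorm(n * p, log(50), 0.4), n, p)
  feat <- c(sprintf("met_%d", seq_len(p - n_is)),
            if (n_is > 0) sprintf("IS_%d", seq_len(n_is)))
  colnames(vals) <- feat
  rownames(vals) <- sprintf("s%d", seq_len(n))
  met_dataset(vals, group = rep_len(groups, n),
              is_internal_standard = c(rep(FALSE, p - n_is),
                                       rep(TRUE, n_is)),
              unit_tag = unit_tag)
}

# Naive O(n^3) complete-linkage agglomeration: returns the sorted merge
# heights.  Independent of stats::hclust.
naive_complete_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# milk-like benchmark design used by the stochastic tests (n = 30
# biological samples, shared multiplicative error sigma_e = 0.3).
bench_design <- function(seed, sigma_e = 0.3, is_group_leak = 0) {
  sim_design(samples_per_group = c(10, 10, 10), n_features = 16,
             n_dominant = 2, n_is = 1, sigma_e = sigma_e,
             sigma_analyte = 0.2, is_group_leak = is_group_leak,
             seed = seed)
}

# Mean per-feature one-way ANOVA F statistic of group on log values.
mean_group_f <- function(d) {
  grp <- factor(d$group)
  mean(apply(log(d$values), 2, function(v) {
    fit <- stats::anova(stats::lm(v ~ grp))
    fit$`F value`[1]
  }))
}
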
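#' Group-wise minimum substitution for structurally missing metabolites
#'
#' First stage of the two-stage missing-value policy.  A (feature, group)
#' block whose missing fraction exceeds `threshold` is treated as a
#' structural (below limit-of-detection) absence: every missing entry in
#' the block is replaced by the minimum observed value of that feature
#' across *all* samples.  Sporadically missing entries (blocks at or below
#' the threshold) are left untouched for [impute_random_forest()].
#'
#' @param d A [met_dataset()] with group labels.
#' @param threshold Missing-fraction cutoff in (0, 1]; a block is
#'   substituted when its missing fraction is strictly greater than this.
#'   Default 0.30.
#' @return A list with elements `dataset` (the substituted
#'   [met_dataset()]) and `report` (an `imputation_report`, see Details).
#'
#' @details The report records, per (feature, group) block, the number of
#'   samples, missing count and fraction, and whether the block was
#'   substituted.  `report$structural_cells` and `report$untouched_cells`
#'   partition the originally missing cells.
#' @export
impute_structural_min <- function(d, threshold = 0.30) {
  stopifnot(inherits(d, "met_dataset"))
  if (!(threshold > 0 && threshold <= 1))
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  vals <- d$values
  grp <- .grouping_factor(d)
  blocks <- expand.grid(feature = d$feature_ids,
                        group = levels(grp),
                        stringsAsFactors = FALSE)
  blocks$n <- NA_integer_
  blocks$n_missing <- NA_integer_
  blocks$missing_fraction <- NA_real_
  blocks$substituted <- FALSE
  structural <- list()
  for (k in seq_len(nrow(blocks))) {
    j <- match(blocks$feature[k], d$feature_ids)
    rows <- which(grp == blocks$group[k])
    miss <- rows[is.na(vals[rows, j])]
    blocks$n[k] <- length(rows)
    blocks$n_missing[k] <- length(miss)
    frac <- length(miss) / length(rows)
    blocks$missing_fraction[k] <- frac
    if (frac > threshold && length(miss)) {
      obs <- vals[, j][!is.na(vals[, j])]
      if (!length(obs))
        stop("feature '", blocks$feature[k], "' has no observed value ",
             "anywhere; no minimum exists for structural substitution",
             call. = FALSE)
      vals[miss, j] <- min(obs)
      blocks$substituted[k] <- TRUE
      structural[[length(structural) + 1L]] <-
        data.frame(sample_id = d$sample_ids[miss],
                   feature = blocks$feature[k],
                   group = blocks$group[k],
                   value = min(obs), stringsAsFactors = FALSE)
    }
  }
  still <- which(is.na(vals), arr.ind = TRUE)
  untouched <- data.frame(
    sample_id = d$sample_ids[still[, 1]],
    feature = d$feature_ids[still[, 2]], stringsAsFactors = FALSE)
  report <- structure(list(
    method = "structural_min",
    parameters = list(threshold = threshold),
    blocks = blocks,
    structural_cells = if (length(structural))
      do.call(rbind, structural) else
        data.frame(sample_id = character(0), feature = character(0),
                   group = character(0), value = numeric(0)),
    untouched_cells = untouched), class = "imputation_report")
  list(dataset = .with_values(d, vals), report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("<imputation_report> method:", x$method, "\n")
  if (x$method == "structural_min") {
    cat("  substituted blocks:", sum(x$blocks$substituted),
        "| cells:", nrow(x$structural_cells),
        "| untouched missing cells:", nrow(x$untouched_cells), "\n")
  } else {
    cat("  imputed cells:", nrow(x$imputed_cells),
        "| iterations:", x$iterations, "\n")
  }
  invisible(x)
}

# QC samples form their own grouping level throughout the package.
.grouping_factor <- function(d) {
  g <- ifelse(d$sample_type == "qc", "QC", d$group)
  factor(g, levels = unique(g))
}

#' Iterative random-forest imputation of sporadically missing values
#'
#' Second stage of the missing-value policy, following the missForest
#' iteration: missing cells are initialised with feature means, then each
#' incomplete feature is regressed on all other features with a regression
#' random forest and its missing entries refilled, sweeping features in
#' order of increasing missingness.  Iteration stops when the normalised
#' squared difference between successive imputations first increases (the
#' previous iterate is returned) or after `max_iter` sweeps.
#'
#' @param d A [met_dataset()]; per-feature missingness should already be
#'   below the structural threshold (run [impute_structural_min()] first).
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum sweeps (default 10).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A list with elements `dataset` and `report`.
#' @export
impute_random_forest <- function(d, n_trees = 100, max_iter = 10,
                                 seed = 1L) {
  stopifnot(inherits(d, "met_dataset"))
  vals <- d$values
  if (ncol(vals) < 2)
    stop("random-forest imputation needs at least 2 features",
         call. = FALSE)
  full_missing <- colSums(!is.na(vals)) == 0
  if (any(full_missing))
    stop("feature(s) fully missing: ",
         paste(d$feature_ids[full_missing], collapse = ", "),
         "; run impute_structural_min() first", call. = FALSE)
  miss_mask <- is.na(vals)
  n_miss <- colSums(miss_mask)
  iterations <- 0L
  if (any(n_miss > 0)) {
    old_seed <- .hold_rng()
    on.exit(.restore_rng(old_seed), add = TRUE)
    set.seed(as.integer(seed))
    # mean initialisation
    cur <- vals
    for (j in which(n_miss > 0))
      cur[miss_mask[, j], j] <- mean(vals[, j], na.rm = TRUE)
    order_j <- order(n_miss)
    order_j <- order_j[n_miss[order_j] > 0]
    prev <- cur
    prev_delta <- Inf
    for (it in seq_len(max_iter)) {
      iterations <- it
      new <- cur
      for (j in order_j) {
        obs <- !miss_mask[, j]
        forest <- .rf_fit(new[obs, -j, drop = FALSE], vals[obs, j],
                          n_trees = n_trees)
        new[miss_mask[, j], j] <-
          .rf_predict(forest, new[miss_mask[, j], -j, drop = FALSE])
      }
      delta <- sum((new[miss_mask] - cur[miss_mask])^2) /
        sum(new[miss_mask]^2)
      if (!is.finite(delta)) delta <- 0
      if (delta > prev_delta) { # first increase: keep previous iterate
        new <- cur
        break
      }
      prev_delta <- delta
      cur <- new
      if (delta == 0) break
    }
    vals <- new
  }
  idx <- which(miss_mask, arr.ind = TRUE)
  report <- structure(list(
    method = "random_forest",
    parameters = list(n_trees = n_trees, max_iter = max_iter, seed = seed),
    iterations = iterations,
    imputed_cells = data.frame(
      sample_id = d$sample_ids[idx[, 1]],
      feature = d$feature_ids[idx[, 2]],
      value = vals[idx], stringsAsFactors = FALSE)),
    class = "imputation_report")
  list(dataset = .with_values(d, vals), report = report)
}

.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- minimal regression random forest -------------------------------------
# CART regression trees on bootstrap samples with random feature subsets
# (mtry = max(1, floor(p/3)), the regression default) and variance-reduction
# splits; nodes of at most `min_node` (5) observations are terminal.  Small
# pure-R implementation: the imputer only ever sees modest metabolomics
# matrices.

.rf_fit <- function(X, y, n_trees = 100, mtry = NULL, min_node = 5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  n <- nrow(X)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- .tree_build(X[idx, , drop = FALSE], y[idx], mtry,
                              min_node)
  }
  list(trees = trees, p = p)
}

.tree_build <- function(X, y, mtry, min_node) {
  # nodes stored in a growing data frame; children appended breadth-first
  nodes <- list()
  queue <- list(list(rows = seq_along(y)))
  node_id <- 0L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    node_id <- node_id + 1L
    rows <- cur$rows
    yv <- y[rows]
    node <- list(var = NA_integer_, cut = NA_real_, left = NA_integer_,
                 right = NA_integer_, pred = mean(yv))
    if (length(rows) > min_node && stats::var(yv) > 0) {
      split <- .best_split(X[rows, , drop = FALSE], yv, mtry, min_node)
      if (!is.null(split)) {
        node$var <- split$var
        node$cut <- split$cut
        go_left <- X[rows, split$var] <= split$cut
        node$left <- -1L  # placeholder, fixed after queueing
        node$right <- -1L
        queue[[length(queue) + 1L]] <- list(rows = rows[go_left],
                                            parent = node_id, side = "L")
        queue[[length(queue) + 1L]] <- list(rows = rows[!go_left],
                                            parent = node_id, side = "R")
      }
    }
    nodes[[node_id]] <- node
    if (!is.null(cur$parent)) {
      if (cur$side == "L") nodes[[cur$parent]]$left <- node_id
      else nodes[[cur$parent]]$right <- node_id
    }
  }
  nodes
}

.best_split <- function(X, y, mtry, min_node) {
  p <- ncol(X)
  vars <- sample.int(p, min(mtry, p))
  best <- NULL
  best_sse <- Inf
  n <- length(y)
  for (v in vars) {
    x <- X[, v]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    cs <- cumsum(ys); tot <- cs[n]
    css <- cumsum(ys^2); totss <- css[n]
    # candidate split after position i (left = 1..i)
    i <- seq_len(n - 1)
    valid <- xs[i] < xs[i + 1]
    if (!any(valid)) next
    i <- i[valid]
    sse <- (css[i] - cs[i]^2 / i) +
      ((totss - css[i]) - (tot - cs[i])^2 / (n - i))
    k <- which.min(sse)
    if (sse[k] < best_sse) {
      best_sse <- sse[k]
      best <- list(var = v, cut = (xs[i[k]] + xs[i[k] + 1]) / 2)
    }
  }
  best
}

.tree_predict <- function(nodes, newdata) {
  vapply(seq_len(nrow(newdata)), function(i) {
    k <- 1L
    repeat {
      nd <- nodes[[k]]
      if (is.na(nd$var)) return(nd$pred)
      k <- if (newdata[i, nd$var] <= nd$cut) nd$left else nd$right
    }
  }, numeric(1))
}

.rf_predict <- function(forest, X) {
  X <- as.matrix(X)
  preds <- lapply(forest$trees, .tree_predict, newdata = X)
  rowMeans(matrix(unlist(preds), nrow = nrow(X)))
}
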
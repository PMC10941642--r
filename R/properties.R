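#' Per-group data-property profile
#'
#' Characterises a processed dataset the way the scheme benchmark does:
#' per (feature, group) it computes the Shapiro-Wilk normality p-value,
#' the moment skewness and the coefficient of variation (CV = sample
#' sd / mean), and aggregates per group the number of normally distributed
#' features (p > 0.05), positively skewed (skewness > 0.5) and negatively
#' skewed (skewness < -0.5) features, and the mean CV (mCV).  QC samples
#' form their own group level.
#'
#' @param d A [met_dataset()]; every group (and QC) must have at least 3
#'   samples, the Shapiro-Wilk minimum.
#' @return A `property_profile`: list with `per_feature` (long data frame
#'   of feature, group, shapiro_p, skewness, cv) and `summary` (per-group
#'   counts and mCV).
#' @export
property_profile <- function(d) {
  stopifnot(inherits(d, "met_dataset"))
  if (anyNA(d$values))
    stop("dataset contains missing values; impute first", call. = FALSE)
  grp <- .grouping_factor(d)
  small <- names(which(table(grp) < 3))
  if (length(small))
    stop("group(s) with fewer than 3 samples (Shapiro-Wilk minimum): ",
         paste(small, collapse = ", "), call. = FALSE)
  rows <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    for (j in seq_along(d$feature_ids)) {
      v <- d$values[sel, j]
      if (length(unique(v)) == 1L) {
        warning("constant values for feature '", d$feature_ids[j],
                "' in group '", g,
                "': Shapiro-Wilk undefined, counted as non-normal",
                call. = FALSE)
        p <- 0
      } else {
        p <- stats::shapiro.test(v)$p.value
      }
      m <- mean(v)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = d$feature_ids[j], group = g,
        shapiro_p = p,
        skewness = skewness_moment(v),
        cv = if (m != 0) stats::sd(v) / m else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_feature <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(levels(grp), function(g) {
    pf <- per_feature[per_feature$group == g, ]
    data.frame(group = g,
               n_normal = sum(pf$shapiro_p > 0.05),
               n_pos_skew = sum(pf$skewness > 0.5),
               n_neg_skew = sum(pf$skewness < -0.5),
               mcv = mean(pf$cv, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_feature = per_feature, summary = summary,
                 n_features = length(d$feature_ids),
                 unit_tag = d$unit_tag), class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat("<property_profile> [", x$unit_tag, "]\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Moment skewness with small-sample factor
#'
#' `g1 * ((n - 1) / n)^(3/2)` where `g1 = m3 / m2^(3/2)` with central
#' moments computed with denominator `n` — the type-3 estimator that is
#' the default of the usual metabolomics tooling.
#'
#' @param x Numeric vector.
#' @return Skewness estimate (`NaN` for constant input).
#' @export
skewness_moment <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  m3 <- mean(xc^3)
  g1 <- m3 / m2^1.5
  g1 * ((n - 1) / n)^1.5
}

#' Fold-difference trend against a reference metabolite
#'
#' For each group and feature, the fold is the ratio of the reference
#' feature's group mean to the feature's group mean, and the direction is
#' the sign of their difference, both on the current (possibly
#' transformed) scale.  By default the reference is the feature with the
#' largest overall mean, since processing methods affect highly abundant
#' metabolites the most.
#'
#' @param d A [met_dataset()] without missing values.
#' @param reference Feature id, or `"auto"` (default).
#' @return A `fold_difference_trend`: list with `reference`, `fold`
#'   (groups x features matrix; `NA` where a non-reference group mean is
#'   zero) and `direction` (matrix of -1/0/1).
#' @export
fold_difference_trend <- function(d, reference = "auto") {
  stopifnot(inherits(d, "met_dataset"))
  if (anyNA(d$values))
    stop("dataset contains missing values; impute first", call. = FALSE)
  grp <- .grouping_factor(d)
  gm <- apply(d$values, 2, function(v) tapply(v, grp, mean))
  gm <- matrix(gm, nrow = nlevels(grp),
               dimnames = list(levels(grp), d$feature_ids))
  if (identical(reference, "auto")) {
    reference <- d$feature_ids[which.max(colMeans(d$values))]
  } else if (!(reference %in% d$feature_ids)) {
    stop("unknown reference feature '", reference, "'", call. = FALSE)
  }
  ref <- gm[, reference]
  fold <- sweep(1 / gm, 1, ref, `*`)
  fold[, reference] <- 1
  fold[!is.finite(fold)] <- NA
  zero <- gm == 0
  zero[, reference] <- FALSE
  fold[zero] <- NA
  dir <- sign(sweep(-gm, 1, ref, `+`))
  structure(list(reference = reference, fold = fold, direction = dir),
            class = "fold_difference_trend")
}

#' Agreement between two fold-difference trends
#'
#' Fraction of (group, feature) cells whose direction signs agree between
#' two trends computed on datasets with the same groups and features.
#'
#' @param a,b `fold_difference_trend` objects.
#' @return Fraction in \[0, 1\].
#' @export
trend_agreement <- function(a, b) {
  stopifnot(inherits(a, "fold_difference_trend"),
            inherits(b, "fold_difference_trend"))
  if (!identical(dim(a$direction), dim(b$direction)))
    stop("trends have different dimensions", call. = FALSE)
  mean(a$direction == b$direction)
}

#' Across-group relative log abundance (RLA)
#'
#' Standardises each metabolite by subtracting its median log value over
#' all samples: `rla[i, j] = log(v[i, j]) - median_i' log(v[i', j])`.
#' RLA boxplots of the per-sample rows are the usual visual check of
#' normalization quality; RLA applies to pre-scaling (positive) data.
#'
#' @param d A [met_dataset()] with strictly positive values.
#' @param log_base 2 (default) or `exp(1)`.
#' @return A list with `rla` (samples x features matrix, per-feature
#'   median exactly 0) and `sample_summary` (per-sample quartiles for
#'   boxplots).
#' @export
rla <- function(d, log_base = 2) {
  stopifnot(inherits(d, "met_dataset"))
  v <- d$values
  if (anyNA(v) || any(v <= 0))
    stop("RLA requires strictly positive values (apply before scaling)",
         call. = FALSE)
  lv <- log(v, base = log_base)
  r <- sweep(lv, 2, apply(lv, 2, stats::median))
  qs <- t(apply(r, 1, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  colnames(qs) <- c("min", "q1", "median", "q3", "max")
  list(rla = r,
       sample_summary = data.frame(sample_id = d$sample_ids,
                                   group = d$group, qs,
                                   stringsAsFactors = FALSE,
                                   row.names = NULL))
}
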
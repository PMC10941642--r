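#' Enumerate the full processing-scheme grid
#'
#' The benchmark grid contains, in deterministic canonical order:
#' 6 transformation-only, 6 scaling-only, 36 transformation-by-scaling,
#' 1 ccmn, 6 ccmn + transformation, 6 ccmn + scaling and 36
#' ccmn + transformation + scaling schemes — 97 in total.
#'
#' @param include_raw Prepend the `"raw"` (all-none) scheme.
#' @return A list of [scheme_id()] objects.
#' @export
enumerate_schemes <- function(include_raw = FALSE) {
  out <- list()
  add <- function(n, t, s) out[[length(out) + 1L]] <<- scheme_id(n, t, s)
  if (include_raw) add("none", "none", "none")
  for (t in TRANSFORM_METHODS) add("none", t, "none")
  for (s in SCALE_METHODS) add("none", "none", s)
  for (t in TRANSFORM_METHODS) for (s in SCALE_METHODS) add("none", t, s)
  add("ccmn", "none", "none")
  for (t in TRANSFORM_METHODS) add("ccmn", t, "none")
  for (s in SCALE_METHODS) add("ccmn", "none", s)
  for (t in TRANSFORM_METHODS) for (s in SCALE_METHODS) add("ccmn", t, s)
  out
}

#' VIP similarity between two processing routes
#'
#' `similarity(x, y) = 1 - sqrt(sum_i (x_i - y_i)^2)` over the two VIP
#' vectors.  Identical vectors score 1 (100 percent); the value is
#' unbounded below and reported as-is.  With `normalize = TRUE` both
#' vectors are first divided by their Euclidean norms, which bounds the
#' distance term by 2 (zero vectors are left unchanged).
#'
#' @param x,y Numeric VIP vectors of equal length.
#' @param normalize Normalise to unit length first (default `FALSE`, the
#'   literal definition).
#' @return The similarity as a fraction (multiply by 100 for percent).
#' @export
vip_similarity <- function(x, y, normalize = FALSE) {
  if (length(x) != length(y))
    stop("VIP vectors have different lengths: ", length(x), " vs ",
         length(y), call. = FALSE)
  if (normalize) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx > 0) x <- x / nx
    if (ny > 0) y <- y / ny
  }
  1 - sqrt(sum((x - y)^2))
}

#' Hierarchical clustering of VIP profiles
#'
#' Agglomerative clustering of the rows of a schemes-by-features VIP
#' matrix using Euclidean distances.
#'
#' @param vip_matrix Numeric matrix, one row per scheme, no missing
#'   values.
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @return An [stats::hclust] object (merge sequence and heights;
#'   cophenetic distances via [stats::cophenetic()]).
#' @export
cluster_vips <- function(vip_matrix, linkage = "complete") {
  vip_matrix <- as.matrix(vip_matrix)
  if (nrow(vip_matrix) < 2)
    stop("clustering needs at least 2 rows", call. = FALSE)
  if (anyNA(vip_matrix))
    stop("VIP matrix contains missing values", call. = FALSE)
  linkage <- match.arg(linkage, c("complete", "average", "ward.D2"))
  stats::hclust(stats::dist(vip_matrix), method = linkage)
}

#' Run the full quantitative-resemblance benchmark
#'
#' Processes the peak-area dataset under every scheme of the grid (plus
#' `"raw"`), fits PLS-DA everywhere, and scores each scheme by the VIP
#' similarity of its fit to the fit on the paired absolute-concentration
#' reference.  Also clusters the VIP profiles and, optionally, computes a
#' PCA over the per-scheme property profiles.
#'
#' Schemes whose preconditions fail on the given data (for example a log
#' transform on data containing zeros) are recorded as skipped with the
#' error message, never silently dropped.
#'
#' @param area Peak-area [met_dataset()] (complete; run imputation
#'   first).  Must carry the IS feature(s) needed by ccmn.
#' @param conc Paired concentration [met_dataset()] with the same sample
#'   ids, groups and analyte feature ids (no IS required).
#' @param n_components PLS components `A` for every fit (default 2).
#' @param np,log_internal,glog_lambda Scheme options, see
#'   [apply_scheme()].
#' @param linkage Clustering linkage for [cluster_vips()].
#' @param compute_properties Also compute [property_profile()] per scheme
#'   and a PCA over the standardized profile matrix (default `TRUE`;
#'   the expensive part of the benchmark).
#' @return An `evaluation_report`: list with `similarity` (data frame per
#'   scheme: similarity, percent, and the normalized variants),
#'   `vip_matrix` (rows `conc`, `raw`, then the grid), `clustering`,
#'   `profile_pca` (when requested), `skipped`, and `config`.
#' @export
run_benchmark <- function(area, conc, n_components = 2, np = NULL,
                          log_internal = TRUE, glog_lambda = "auto",
                          linkage = "complete",
                          compute_properties = TRUE) {
  stopifnot(inherits(area, "met_dataset"), inherits(conc, "met_dataset"))
  analyte_ids <- area$feature_ids[!area$is_internal_standard]
  .check_keys(area$sample_ids, conc$sample_ids, "sample ids")
  .check_keys(analyte_ids,
              conc$feature_ids[!conc$is_internal_standard],
              "analyte feature ids")
  if (!identical(area$group, conc$group))
    stop("group labels differ between area and conc datasets",
         call. = FALSE)

  ref_fit <- run_plsda(conc, n_components = n_components)
  ref_vip <- ref_fit$vip[analyte_ids]

  schemes <- enumerate_schemes(include_raw = TRUE)
  labels <- vapply(schemes, format, character(1))
  vips <- matrix(NA_real_, length(schemes), length(analyte_ids),
                 dimnames = list(labels, analyte_ids))
  skipped <- data.frame(scheme = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  glog_lambdas <- list()
  processed <- list()
  for (k in seq_along(schemes)) {
    # scheme-level warnings (e.g. level scaling of sign-mixed data) are
    # expected across a 97-scheme sweep and would drown the console
    res <- tryCatch(suppressWarnings({
      pd <- apply_scheme(area, schemes[[k]], np = np,
                         log_internal = log_internal,
                         glog_lambda = glog_lambda)
      lam <- attr(pd, "glog_parameter")
      if (!is.null(lam)) glog_lambdas[[labels[k]]] <- lam$lambda
      # drop any IS columns the scheme left untouched
      pda <- if (any(pd$is_internal_standard))
        split_standards(pd)$analytes else pd
      processed[[labels[k]]] <- pda
      fit <- run_plsda(pda, n_components = n_components)
      fit$vip[analyte_ids]
    }), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(scheme = labels[k],
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE))
    } else {
      vips[k, ] <- res
    }
  }

  ok <- !is.na(vips[, 1])
  sim <- vapply(which(ok), function(k)
    vip_similarity(vips[k, ], ref_vip), numeric(1))
  sim_norm <- vapply(which(ok), function(k)
    vip_similarity(vips[k, ], ref_vip, normalize = TRUE), numeric(1))
  similarity <- data.frame(
    scheme = labels[ok],
    similarity = sim,
    percent = 100 * sim,
    similarity_normalized = sim_norm,
    percent_normalized = 100 * sim_norm,
    stringsAsFactors = FALSE)

  vip_full <- rbind(conc = ref_vip, vips[ok, , drop = FALSE])
  clustering <- cluster_vips(vip_full, linkage = linkage)

  profile_pca <- NULL
  profiles <- NULL
  if (compute_properties) {
    profiles <- lapply(processed, function(pd)
      tryCatch(property_profile(pd), error = function(e) NULL,
               warning = function(w) suppressWarnings(
                 property_profile(pd))))
    keep <- !vapply(profiles, is.null, logical(1))
    profiles <- profiles[keep]
    if (length(profiles) >= 3) {
      pm <- t(vapply(profiles, .flatten_profile,
                     numeric(length(.flatten_profile(profiles[[1]])))))
      rownames(pm) <- names(profiles)
      sds <- apply(pm, 2, stats::sd)
      pm <- pm[, sds > 0, drop = FALSE]
      pm <- scale(pm)
      profile_pca <- run_pca(pm, n_components = 2, center = FALSE)
    }
  }

  structure(list(similarity = similarity,
                 vip_matrix = vip_full,
                 reference_vip = ref_vip,
                 clustering = clustering,
                 profile_pca = profile_pca,
                 profiles = profiles,
                 skipped = skipped,
                 config = list(n_components = n_components, np = np,
                               log_internal = log_internal,
                               glog_lambda = glog_lambda,
                               glog_lambdas_used = glog_lambdas,
                               linkage = linkage,
                               n_schemes = length(schemes) - 1L)),
            class = "evaluation_report")
}

.flatten_profile <- function(pr) {
  s <- pr$summary
  v <- c(t(as.matrix(s[, c("n_normal", "n_pos_skew", "n_neg_skew",
                           "mcv")])))
  names(v) <- as.vector(outer(c("n_normal", "n_pos_skew", "n_neg_skew",
                                "mcv"), s$group, paste, sep = "."))
  v
}

.check_keys <- function(a, b, what) {
  extra <- setdiff(a, b); missing <- setdiff(b, a)
  if (length(extra) || length(missing))
    stop(what, " differ between datasets; only in first: ",
         paste(extra, collapse = ", "), "; only in second: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(a, b))
    stop(what, " are in different orders", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$config$n_schemes, "grid schemes;",
      nrow(x$similarity), "evaluated,", nrow(x$skipped), "skipped\n")
  top <- utils::head(x$similarity[order(-x$similarity$similarity), ], 5)
  cat("  top schemes by VIP similarity to the concentration reference:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-22s %7.2f%%\n", top$scheme[i], top$percent[i]))
  invisible(x)
}
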
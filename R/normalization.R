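# Internal-standard based normalization.
#
# Both ccmn and nomis model the log peak area of each analyte as signal
# plus a sample-specific systematic error that is also carried by the
# spiked internal standards (ISs).  nomis regresses analytes directly on
# the ISs; ccmn first removes from the ISs any variance explained by the
# study design (one-hot group matrix, QC as its own level), so biological
# variation that leaks into the ISs is not subtracted from the analytes.

#' Cross-contribution compensating multiple standard normalization (ccmn)
#'
#' Removes sample-wise systematic error estimated from the internal
#' standards, after orthogonalising the IS variation against the study
#' design so that group-correlated ("informative") variation is retained.
#'
#' The algorithm: (1) column-centre the log IS matrix; (2) project it onto
#' the orthogonal complement of the one-hot group design; (3) take the
#' first `np` principal-component scores of the residual as the estimated
#' error components; (4) regress each centred log analyte on the scores by
#' ordinary least squares and subtract the fit; (5) restore analyte means
#' and exponentiate back to the original scale.  IS columns are dropped
#' from the returned dataset; the model object retains everything needed
#' to audit the correction.
#'
#' @param d A [met_dataset()] with at least one IS-flagged feature and
#'   group labels.
#' @param np Number of error components to retain, at most the number of
#'   ISs.  `NULL` (default) uses `min(2, number of ISs)`.
#' @param log_internal Compute on the natural-log scale and back-transform
#'   (default `TRUE`; requires strictly positive values).
#' @return A list with elements `dataset` (analytes only, corrected) and
#'   `model` (a `normalization_model`).
#' @examples
#' d <- simulate_pair(sim_design(samples_per_group = c(5, 5),
#'                               n_features = 6, seed = 7))$area
#' out <- normalize_ccmn(d)
#' out$model
#' @export
normalize_ccmn <- function(d, np = NULL, log_internal = TRUE) {
  parts <- split_standards(d)
  X <- parts$analytes$values
  S <- parts$standards$values
  q <- ncol(S)
  if (is.null(np)) np <- min(2L, q)
  if (np < 1 || np > q)
    stop("`np` must be between 1 and the number of internal standards (",
         q, ")", call. = FALSE)
  .check_positive(cbind(X, S), d, log_internal)

  Z <- if (log_internal) log(X) else X
  L <- if (log_internal) log(S) else S
  Lc <- scale(L, center = TRUE, scale = FALSE)

  G <- stats::model.matrix(~ 0 + g,
                           data = data.frame(g = .grouping_factor(d)))
  # residual of the IS matrix after removing design-explained variance
  PG <- G %*% .pinv(crossprod(G)) %*% t(G)
  R <- Lc - PG %*% Lc

  sv <- svd(R)
  keep <- seq_len(min(np, length(sv$d)))
  np <- length(keep)
  # zero-variance residual (e.g. constant IS): no error signal to remove
  dvals <- sv$d[keep]
  dvals[dvals < max(sv$d[1], 1) * 1e-10] <- 0
  Tz <- sv$u[, keep, drop = FALSE] %*% diag(dvals, nrow = np)

  mu <- colMeans(Z)
  Zc <- sweep(Z, 2, mu)
  B <- .pinv(crossprod(Tz)) %*% crossprod(Tz, Zc)
  Zadj <- Zc - Tz %*% B
  out <- sweep(Zadj, 2, mu, `+`)
  if (log_internal) out <- exp(out)
  dimnames(out) <- dimnames(X)

  model <- structure(list(
    method = "ccmn", np = np, log_internal = log_internal,
    design_levels = colnames(G),
    scores = Tz, coefficients = B,
    analyte_means = mu,
    standards = S,
    back_transformed = log_internal), class = "normalization_model")
  list(dataset = .with_values(parts$analytes, out,
                              unit_tag = "processed:ccmn"),
       model = model)
}

#' Normalization using (an optimal combination of) internal standards
#' (nomis)
#'
#' Regresses each centred log analyte on the centred log IS matrix by
#' least squares and subtracts the fitted values, then back-transforms to
#' the original scale.  Unlike [normalize_ccmn()], there is no design
#' orthogonalisation, so IS variation correlated with the study factor is
#' removed along with the systematic error.
#'
#' @inheritParams normalize_ccmn
#' @return A list with elements `dataset` and `model`.
#' @export
normalize_nomis <- function(d, log_internal = TRUE) {
  parts <- split_standards(d)
  X <- parts$analytes$values
  S <- parts$standards$values
  .check_positive(cbind(X, S), d, log_internal)
  Z <- if (log_internal) log(X) else X
  L <- if (log_internal) log(S) else S
  Lc <- scale(L, center = TRUE, scale = FALSE)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2, mu)
  B <- .pinv(crossprod(Lc)) %*% crossprod(Lc, Zc)
  Zadj <- Zc - Lc %*% B
  out <- sweep(Zadj, 2, mu, `+`)
  if (log_internal) out <- exp(out)
  dimnames(out) <- dimnames(X)
  model <- structure(list(
    method = "nomis", np = ncol(S), log_internal = log_internal,
    coefficients = B, analyte_means = mu, standards = S,
    back_transformed = log_internal), class = "normalization_model")
  list(dataset = .with_values(parts$analytes, out,
                              unit_tag = "processed:nomis"),
       model = model)
}

#' Single internal-standard ratio normalization
#'
#' Divides every analyte value in a sample by that sample's response of
#' one internal standard — the classical "normalize to the spike-in"
#' correction.
#'
#' @param d A [met_dataset()].
#' @param is_feature Feature id of the IS to use; defaults to the single
#'   IS-flagged feature when there is exactly one.
#' @return A [met_dataset()] of analytes only.
#' @export
normalize_is_ratio <- function(d, is_feature = NULL) {
  parts <- split_standards(d)
  if (is.null(is_feature)) {
    if (ncol(parts$standards$values) != 1L)
      stop("multiple internal standards present; name one via `is_feature`",
           call. = FALSE)
    is_feature <- parts$standards$feature_ids[1]
  }
  if (!(is_feature %in% d$feature_ids[d$is_internal_standard]))
    stop("'", is_feature, "' is not an IS-flagged feature", call. = FALSE)
  s <- d$values[, is_feature]
  bad <- which(!is.na(s) & s <= 0)
  if (length(bad) || anyNA(s))
    stop("internal standard '", is_feature,
         "' has non-positive or missing values in sample(s): ",
         paste(d$sample_ids[c(bad, which(is.na(s)))], collapse = ", "),
         call. = FALSE)
  out <- sweep(parts$analytes$values, 1, s, `/`)
  .with_values(parts$analytes, out, unit_tag = "processed:is_ratio")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("<normalization_model> method:", x$method,
      "| components:", x$np,
      "| log-internal:", x$log_internal, "\n")
  invisible(x)
}

.check_positive <- function(vals, d, log_internal) {
  if (anyNA(vals))
    stop("dataset contains missing values; impute before normalization",
         call. = FALSE)
  if (log_internal) {
    bad <- which(vals <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "non-positive value at sample '%s', feature '%s': log-scale %s",
        rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]],
        "normalization requires strictly positive data"), call. = FALSE)
  }
  invisible(TRUE)
}

# Moore-Penrose pseudo-inverse via SVD; tolerant of rank deficiency.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > max(s$d[1], 0) * tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
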
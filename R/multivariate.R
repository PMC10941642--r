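#' Principal component analysis
#'
#' Singular-value decomposition of the (centred, optionally unit-scaled)
#' data matrix, with a deterministic sign convention: within each
#' component the loading element of largest magnitude is positive.
#'
#' @param d A [met_dataset()] or numeric matrix without missing values.
#' @param n_components Number of components to return; at most
#'   `min(n - 1, p)`.
#' @param center,unit_scale Column centring (default `TRUE`) and unit
#'   variance scaling (default `FALSE`).
#' @return A `pca_result` with `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance` (fractions,
#'   non-increasing, summing to at most 1), and the settings used.
#' @export
run_pca <- function(d, n_components = 2, center = TRUE,
                    unit_scale = FALSE) {
  X <- if (inherits(d, "met_dataset")) d$values else as.matrix(d)
  if (anyNA(X))
    stop("missing values present; impute before PCA", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop("n_components must be <= min(n - 1, p) = ", min(n - 1, p),
         call. = FALSE)
  Xc <- scale(X, center = center, scale = FALSE)
  if (unit_scale) {
    s <- apply(Xc, 2, stats::sd)
    s[s == 0] <- 1
    Xc <- sweep(Xc, 2, s, `/`)
  }
  sv <- svd(Xc)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = n_components)
  for (a in k) { # sign convention
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", k))
  dimnames(loadings) <- list(colnames(X), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[k],
                 all_explained_variance = ev,
                 center = center, unit_scale = unit_scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components; explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance),
             collapse = ", "), "\n")
  invisible(x)
}

#' PLS-DA with VIP scores
#'
#' Partial least squares discriminant analysis by NIPALS PLS2 against the
#' one-hot group response.  X and Y are column-mean-centred; no additional
#' scaling is applied (the processing scheme under test owns any scaling).
#' Pooled QC samples are excluded from the class model by default since
#' they are not a biological class.
#'
#' The variable importance in projection of feature `j` is
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )`
#' with `SSY_a = (t_a' t_a)(q_a' q_a)`, so the squared VIPs average to 1.
#'
#' @param d A [met_dataset()] with at least two group levels among non-QC
#'   samples and no missing values.
#' @param n_components Number of latent components `A` (default 2);
#'   truncated with a warning if the data rank is lower.
#' @param qc_policy `"exclude"` (default) or `"include"` QC samples in the
#'   class model (when included they form their own class).
#' @return A `plsda_result` with weights `W`, scores `T`, X-loadings `P`,
#'   Y-loadings `Q`, per-component explained Y sum of squares `ssy`, and
#'   the VIP vector `vip` (named by feature).
#' @export
run_plsda <- function(d, n_components = 2, qc_policy = c("exclude",
                                                         "include")) {
  stopifnot(inherits(d, "met_dataset"))
  qc_policy <- match.arg(qc_policy)
  keep <- if (qc_policy == "exclude") d$sample_type != "qc"
          else rep(TRUE, length(d$sample_ids))
  X <- d$values[keep, , drop = FALSE]
  if (anyNA(X))
    stop("missing values present; impute before PLS-DA", call. = FALSE)
  grp <- if (qc_policy == "include") .grouping_factor(d)[keep]
         else factor(d$group[keep], levels = unique(d$group[keep]))
  if (nlevels(grp) < 2)
    stop("PLS-DA needs at least 2 group levels, got ", nlevels(grp),
         call. = FALSE)
  Y <- stats::model.matrix(~ 0 + grp)
  colnames(Y) <- levels(grp)

  fit <- .nipals_pls2(scale(X, center = TRUE, scale = FALSE),
                      scale(Y, center = TRUE, scale = FALSE),
                      n_components)
  p <- ncol(X)
  Wn <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), `/`)
  vip <- sqrt(p * as.vector(Wn^2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- colnames(X)
  structure(list(n_components = fit$A, W = fit$W, T = fit$T, P = fit$P,
                 Q = fit$Q, ssy = fit$ssy, vip = vip,
                 groups = levels(grp), qc_policy = qc_policy,
                 feature_ids = colnames(X)),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat("<plsda_result>", x$n_components, "components,",
      length(x$vip), "features, groups:",
      paste(x$groups, collapse = ", "), "\n")
  cat("  top VIP:",
      paste(sprintf("%s=%.2f", names(sort(x$vip, decreasing = TRUE))[1:3],
                    sort(x$vip, decreasing = TRUE)[1:3]),
            collapse = ", "), "\n")
  invisible(x)
}

# NIPALS PLS2 with p-loading deflation of X and q-deflation of Y.
.nipals_pls2 <- function(X, Y, A, tol = 1e-12, max_iter = 500) {
  n <- nrow(X); p <- ncol(X)
  A_max <- min(n - 1, p, A)
  W <- matrix(0, p, A_max); P <- matrix(0, p, A_max)
  Tm <- matrix(0, n, A_max); Q <- matrix(0, ncol(Y), A_max)
  ssy <- numeric(A_max)
  a <- 0L
  for (comp in seq_len(A_max)) {
    u <- Y[, which.max(colSums(Y^2))]
    if (sum(u^2) < tol) break
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- X %*% w
      q <- crossprod(Y, t) / sum(t^2)
      u <- Y %*% q / sum(q^2)
      if (sum((t - t_old)^2) / max(sum(t^2), 1e-300) < tol) break
      t_old <- t
    }
    if (sqrt(sum(w^2)) < 1e-14 || sum(t^2) < 1e-24) break
    # deterministic sign: largest-|w| element positive
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; t <- -t; q <- -q }
    pv <- crossprod(X, t) / sum(t^2)
    a <- comp
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pv; Q[, a] <- q
    ssy[a] <- sum(t^2) * sum(q^2)
    X <- X - t %*% t(pv)
    Y <- Y - t %*% t(q)
  }
  if (a == 0L)
    stop("no PLS component could be extracted (degenerate data)",
         call. = FALSE)
  if (a < A)
    warning("requested ", A, " components but data rank supports ", a,
            "; truncated", call. = FALSE)
  k <- seq_len(a)
  list(A = a, W = W[, k, drop = FALSE], T = Tm[, k, drop = FALSE],
       P = P[, k, drop = FALSE], Q = Q[, k, drop = FALSE], ssy = ssy[k])
}

#' Discriminant features by VIP threshold
#'
#' @param r A `plsda_result`.
#' @param threshold VIP cutoff (features with `VIP >= threshold` are
#'   returned, sorted by decreasing VIP).
#' @return Character vector of feature ids.
#' @export
vip_discriminants <- function(r, threshold = 1.5) {
  stopifnot(inherits(r, "plsda_result"))
  v <- sort(r$vip[r$vip >= threshold], decreasing = TRUE)
  names(v)
}
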
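#' @rdname transform_features
#' @export
TRANSFORM_METHODS <- c("cube", "log2", "log10", "glog2", "glog10", "sqrt")

#' @rdname scale_features
#' @export
SCALE_METHODS <- c("auto", "level", "pareto", "power", "range", "vast")

#' Element-wise data transformations
#'
#' Applies one of the six transformations used to reduce right skewness
#' and compress the spread between large and small intensities:
#' cube root (`sign(x) |x|^(1/3)`), `log2`, `log10`, generalized log
#' (`glog2`, `glog10`) and square root.  The generalized log is
#' `glog_B(x; lambda) = log_B((x + sqrt(x^2 + lambda)) / 2)`; it accepts
#' zero and negative values and tends to `log_B(x)` as `lambda -> 0`.
#'
#' Domain rules: `log2`/`log10` require strictly positive values, `sqrt`
#' requires non-negative values, cube and glog accept zero and negative
#' values.
#'
#' @param d A [met_dataset()].
#' @param method One of `TRANSFORM_METHODS`.
#' @param glog_lambda Glog parameter: `"auto"` (default, see
#'   [select_glog_lambda()]), a non-negative number, or a `glog_parameter`.
#' @return The transformed [met_dataset()]; for glog methods the chosen
#'   lambda is attached as attribute `"glog_parameter"`.
#' @export
transform_features <- function(d, method, glog_lambda = "auto") {
  stopifnot(inherits(d, "met_dataset"))
  method <- match.arg(method, TRANSFORM_METHODS)
  x <- d$values
  lam <- NULL
  out <- switch(method,
    cube = sign(x) * abs(x)^(1 / 3),
    sqrt = {
      .check_domain(x, x < 0, method,
                    "square root requires non-negative values")
      sqrt(x)
    },
    log2 = ,
    log10 = {
      .check_domain(x, x <= 0, method,
                    "log transformations require strictly positive values")
      if (method == "log2") log2(x) else log10(x)
    },
    glog2 = ,
    glog10 = {
      lam <- if (identical(glog_lambda, "auto")) select_glog_lambda(d)
             else if (inherits(glog_lambda, "glog_parameter")) glog_lambda
             else glog_parameter(glog_lambda, rule = "user")
      base <- if (method == "glog2") 2 else 10
      log((x + sqrt(x^2 + lam$lambda)) / 2, base = base)
    })
  res <- .with_values(d, out, unit_tag = .tag_step(d$unit_tag, method))
  if (!is.null(lam)) attr(res, "glog_parameter") <- lam
  res
}

#' Generalized-log parameter
#'
#' @param lambda Non-negative transform parameter, in squared-intensity
#'   units.
#' @param rule Name of the selection rule that produced it.
#' @return A `glog_parameter` object.
#' @export
glog_parameter <- function(lambda, rule = "user") {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("glog lambda must be a single non-negative number", call. = FALSE)
  structure(list(lambda = lambda, rule = rule), class = "glog_parameter")
}

#' @export
print.glog_parameter <- function(x, ...) {
  cat("<glog_parameter> lambda =", format(x$lambda), "( rule:", x$rule,
      ")\n")
  invisible(x)
}

#' Per-dataset glog parameter selection
#'
#' Default rule: lambda is the square of the smallest strictly positive
#' value in the dataset, so the transform behaves like a plain log over
#' the observed dynamic range while remaining defined at zero.
#'
#' @param d A [met_dataset()] with at least one strictly positive value.
#' @return A [glog_parameter()].
#' @export
select_glog_lambda <- function(d) {
  v <- d$values[!is.na(d$values) & d$values > 0]
  if (!length(v))
    stop("no strictly positive value in the dataset; cannot select a ",
         "glog lambda", call. = FALSE)
  glog_parameter(min(v)^2, rule = "min_positive_squared")
}

#' Per-feature scaling
#'
#' Applies one of the six scaling methods.  With per-feature mean `m`,
#' sample (n-1) standard deviation `s`, maximum `M` and minimum `mn`:
#' \describe{
#'   \item{auto}{`(x - m) / s` — unit variance}
#'   \item{level}{`(x - m) / m` — response relative to the mean}
#'   \item{pareto}{`(x - m) / sqrt(s)` — tempered variance scaling}
#'   \item{power}{`sqrt(x) - mean(sqrt(x))` — square-root transform plus
#'     mean subtraction (requires non-negative data)}
#'   \item{range}{`(x - m) / (M - mn)`}
#'   \item{vast}{`((x - m) / s) * (m / s)` — auto scaling weighted by the
#'     inverse coefficient of variation}
#' }
#' Statistics are computed over all samples (QCs included) of the dataset
#' being processed.
#'
#' @param d A [met_dataset()].
#' @param method One of `SCALE_METHODS`.
#' @return The scaled [met_dataset()].
#' @export
scale_features <- function(d, method) {
  stopifnot(inherits(d, "met_dataset"))
  method <- match.arg(method, SCALE_METHODS)
  x <- d$values
  if (anyNA(x))
    stop("dataset contains missing values; impute before scaling",
         call. = FALSE)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  .check_feature_stat <- function(bad, stat) {
    if (any(bad))
      stop(method, " scaling undefined for feature(s) ",
           paste(d$feature_ids[bad], collapse = ", "), ": ", stat,
           call. = FALSE)
  }
  out <- switch(method,
    auto = {
      .check_feature_stat(s == 0, "constant column (sd = 0)")
      sweep(sweep(x, 2, m), 2, s, `/`)
    },
    level = {
      .check_feature_stat(m == 0, "zero mean")
      if (any(m < 0))
        warning("level scaling with negative feature mean(s): ",
                paste(d$feature_ids[m < 0], collapse = ", "))
      sweep(sweep(x, 2, m), 2, m, `/`)
    },
    pareto = {
      .check_feature_stat(s == 0, "constant column (sd = 0)")
      sweep(sweep(x, 2, m), 2, sqrt(s), `/`)
    },
    power = {
      .check_domain(x, x < 0, "power",
                    "power scaling requires non-negative values")
      r <- sqrt(x)
      sweep(r, 2, colMeans(r))
    },
    range = {
      rg <- apply(x, 2, function(v) max(v) - min(v))
      .check_feature_stat(rg == 0, "zero range (max = min)")
      sweep(sweep(x, 2, m), 2, rg, `/`)
    },
    vast = {
      .check_feature_stat(s == 0, "constant column (sd = 0)")
      sweep(sweep(sweep(x, 2, m), 2, s, `/`), 2, m / s, `*`)
    })
  .with_values(d, out, unit_tag = .tag_step(d$unit_tag, method))
}

.check_domain <- function(x, bad, method, rule) {
  idx <- which(!is.na(x) & bad, arr.ind = TRUE)
  if (nrow(idx))
    stop(sprintf("%s: value %g at sample '%s', feature '%s' — %s",
                 method, x[idx[1, 1], idx[1, 2]],
                 rownames(x)[idx[1, 1]], colnames(x)[idx[1, 2]], rule),
         call. = FALSE)
  invisible(TRUE)
}

.tag_step <- function(tag, step) paste(tag, step, sep = "|")

# ---- processing schemes ---------------------------------------------------

#' Processing-scheme identifiers
#'
#' A scheme is an ordered recipe of an optional normalization
#' (`none`, `ccmn`, `nomis`, `is_ratio`), an optional transformation and
#' an optional scaling, always applied in that order.  The canonical
#' string form is `"norm+transform+scale"`; the all-`none` recipe prints
#' as `"raw"`.
#'
#' @param normalization,transformation,scaling Component method names
#'   (`"none"` for an absent stage).
#' @return A `scheme_id` object.
#' @examples
#' scheme_id("ccmn", "sqrt", "none")
#' parse_scheme("ccmn+sqrt+none")
#' format(scheme_id())  # "raw"
#' @export
scheme_id <- function(normalization = "none", transformation = "none",
                      scaling = "none") {
  normalization <- match.arg(normalization,
                             c("none", "ccmn", "nomis", "is_ratio"))
  transformation <- match.arg(transformation,
                              c("none", TRANSFORM_METHODS))
  scaling <- match.arg(scaling, c("none", SCALE_METHODS))
  structure(list(normalization = normalization,
                 transformation = transformation,
                 scaling = scaling), class = "scheme_id")
}

#' @rdname scheme_id
#' @param x A canonical scheme string such as `"ccmn+sqrt+none"`, a
#'   single-stage shorthand (`"sqrt"`), or `"raw"`.
#' @export
parse_scheme <- function(x) {
  if (inherits(x, "scheme_id")) return(x)
  x <- as.character(x)
  if (identical(x, "raw")) return(scheme_id())
  parts <- strsplit(x, "+", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    p <- parts[1]
    if (p %in% c("ccmn", "nomis", "is_ratio"))
      return(scheme_id(normalization = p))
    if (p %in% TRANSFORM_METHODS)
      return(scheme_id(transformation = p))
    if (p %in% SCALE_METHODS)
      return(scheme_id(scaling = p))
    stop("unknown scheme component: '", p, "'", call. = FALSE)
  }
  if (length(parts) != 3)
    stop("scheme string must be 'norm+transform+scale' or 'raw', got '",
         x, "'", call. = FALSE)
  scheme_id(parts[1], parts[2], parts[3])
}

#' @export
format.scheme_id <- function(x, ...) {
  if (x$normalization == "none" && x$transformation == "none" &&
      x$scaling == "none") return("raw")
  paste(x$normalization, x$transformation, x$scaling, sep = "+")
}

#' @export
print.scheme_id <- function(x, ...) {
  cat("<scheme_id>", format(x), "\n")
  invisible(x)
}

#' Apply a full processing scheme
#'
#' Runs the scheme stages in the fixed order normalization, then
#' transformation, then scaling, and tags the result with the canonical
#' scheme string.  Errors raised by a stage are re-signalled with the
#' stage name prepended.
#'
#' @param d A [met_dataset()].
#' @param scheme A [scheme_id()] or canonical scheme string.
#' @param np,log_internal Passed to [normalize_ccmn()].
#' @param glog_lambda Passed to [transform_features()].
#' @param is_feature Passed to [normalize_is_ratio()].
#' @return The processed [met_dataset()] with
#'   `unit_tag = "processed:<scheme>"` (or the input unchanged for
#'   `"raw"`).
#' @export
apply_scheme <- function(d, scheme, np = NULL, log_internal = TRUE,
                         glog_lambda = "auto", is_feature = NULL) {
  scheme <- parse_scheme(scheme)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage (", format(scheme), "): ", conditionMessage(e),
           call. = FALSE))
  }
  out <- d
  lam <- NULL
  if (scheme$normalization != "none")
    out <- stage("normalization", switch(scheme$normalization,
      ccmn = normalize_ccmn(out, np = np,
                            log_internal = log_internal)$dataset,
      nomis = normalize_nomis(out, log_internal = log_internal)$dataset,
      is_ratio = normalize_is_ratio(out, is_feature = is_feature)))
  if (scheme$transformation != "none") {
    out <- stage("transformation",
                 transform_features(out, scheme$transformation,
                                    glog_lambda = glog_lambda))
    lam <- attr(out, "glog_parameter")
  }
  if (scheme$scaling != "none")
    out <- stage("scaling", scale_features(out, scheme$scaling))
  if (format(scheme) != "raw")
    out$unit_tag <- paste0("processed:", format(scheme))
  if (!is.null(lam)) attr(out, "glog_parameter") <- lam
  out
}
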
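#' Metabolomics dataset container
#'
#' `met_dataset()` bundles a samples-by-features intensity (or
#' concentration) matrix with the sample and feature metadata every other
#' operation in the package needs: the biological group factor, the sample
#' type (study sample vs. pooled QC), optional replicate labels, and
#' per-feature internal-standard (IS) flags.
#'
#' Missing values are `NA` and are distinct from zero: a zero is a measured
#' value, an `NA` is an absent measurement (for example a below-LOD signal).
#'
#' @param values Numeric matrix, rows = samples, columns = features.
#'   Row and column names, when present, are used as sample/feature ids
#'   unless `sample_ids`/`feature_ids` are given.
#' @param group Character or factor of biological group labels, one per
#'   sample.
#' @param sample_type Character vector with entries `"sample"` or `"qc"`,
#'   one per sample (recycled if length 1).
#' @param replicate Optional replicate labels, one per sample.
#' @param is_internal_standard Logical vector, one per feature (recycled if
#'   length 1), flagging spiked-in internal standards.
#' @param sample_ids,feature_ids Optional explicit id vectors; must be
#'   unique.
#' @param unit_tag Free-text tag describing the measurement scale, e.g.
#'   `"area"`, `"concentration"` or `"processed:<scheme>"`.
#'
#' @return An object of class `met_dataset`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `group`, `sample_type`,
#'   `replicate`, `is_internal_standard` and `unit_tag`.
#' @examples
#' m <- matrix(rlnorm(12), 4, 3, dimnames = list(paste0("s", 1:4),
#'                                               c("A", "B", "IS1")))
#' d <- met_dataset(m, group = c("x", "x", "y", "y"),
#'                  is_internal_standard = c(FALSE, FALSE, TRUE))
#' d
#' @export
met_dataset <- function(values, group,
                        sample_type = "sample",
                        replicate = NULL,
                        is_internal_standard = FALSE,
                        sample_ids = NULL,
                        feature_ids = NULL,
                        unit_tag = "area") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)

  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- sprintf("feature_%d", seq_len(p))
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  .check_unique(sample_ids, "sample")
  .check_unique(feature_ids, "feature")
  if (length(sample_ids) != n)
    stop("length(sample_ids) != number of rows of `values`", call. = FALSE)
  if (length(feature_ids) != p)
    stop("length(feature_ids) != number of columns of `values`",
         call. = FALSE)

  group <- as.character(group)
  if (length(group) != n)
    stop("`group` must have one label per sample (", n, "), got ",
         length(group), call. = FALSE)
  if (length(sample_type) == 1L) sample_type <- rep(sample_type, n)
  sample_type <- as.character(sample_type)
  if (length(sample_type) != n)
    stop("`sample_type` must have one entry per sample", call. = FALSE)
  bad <- setdiff(unique(sample_type), c("sample", "qc"))
  if (length(bad))
    stop("`sample_type` entries must be 'sample' or 'qc'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(replicate)) {
    replicate <- as.character(replicate)
    if (length(replicate) != n)
      stop("`replicate` must have one label per sample", call. = FALSE)
  }
  if (length(is_internal_standard) == 1L)
    is_internal_standard <- rep(is_internal_standard, p)
  is_internal_standard <- as.logical(is_internal_standard)
  if (length(is_internal_standard) != p || anyNA(is_internal_standard))
    stop("`is_internal_standard` must be a logical vector of length ", p,
         call. = FALSE)

  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values,
                 sample_ids = sample_ids,
                 feature_ids = feature_ids,
                 group = group,
                 sample_type = sample_type,
                 replicate = replicate,
                 is_internal_standard = is_internal_standard,
                 unit_tag = as.character(unit_tag)[1]),
            class = "met_dataset")
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.met_dataset <- function(x, ...) {
  cat("<met_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " features [", x$unit_tag, "]\n", sep = "")
  cat("  groups: ", paste(sprintf("%s(%d)", names(table(x$group)),
                                  table(x$group)), collapse = ", "), "\n",
      sep = "")
  n_qc <- sum(x$sample_type == "qc")
  if (n_qc) cat("  QC samples: ", n_qc, "\n", sep = "")
  n_is <- sum(x$is_internal_standard)
  if (n_is)
    cat("  internal standards: ",
        paste(x$feature_ids[x$is_internal_standard], collapse = ", "),
        "\n", sep = "")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  missing cells: ", n_na, "\n", sep = "")
  invisible(x)
}

#' @export
dim.met_dataset <- function(x) dim(x$values)

# Internal: subset a met_dataset by sample index and/or feature index,
# keeping metadata aligned.
.subset_dataset <- function(d, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- seq_along(d$sample_ids)
  if (is.null(features)) features <- seq_along(d$feature_ids)
  met_dataset(d$values[samples, features, drop = FALSE],
              group = d$group[samples],
              sample_type = d$sample_type[samples],
              replicate = if (!is.null(d$replicate)) d$replicate[samples],
              is_internal_standard = d$is_internal_standard[features],
              sample_ids = d$sample_ids[samples],
              feature_ids = d$feature_ids[features],
              unit_tag = d$unit_tag)
}

# Internal: replace the value matrix, keeping metadata; optionally retag.
.with_values <- function(d, values, unit_tag = d$unit_tag,
                         is_internal_standard = NULL) {
  stopifnot(nrow(values) == length(d$sample_ids))
  if (is.null(is_internal_standard)) {
    if (ncol(values) == length(d$feature_ids)) {
      is_internal_standard <- d$is_internal_standard
    } else stop("feature flags needed when feature count changes")
  }
  met_dataset(values, group = d$group, sample_type = d$sample_type,
              replicate = d$replicate,
              is_internal_standard = is_internal_standard,
              sample_ids = d$sample_ids,
              feature_ids = colnames(values),
              unit_tag = unit_tag)
}

#' Split a dataset into analytes and internal standards
#'
#' Partitions the features of a dataset by the internal-standard flag.
#' Sample metadata is shared; concatenating the two returned feature sets
#' reproduces the input up to column order.
#'
#' @param d A [met_dataset()].
#' @return A list with elements `analytes` and `standards`, both
#'   `met_dataset` objects.
#' @export
split_standards <- function(d) {
  stopifnot(inherits(d, "met_dataset"))
  if (!any(d$is_internal_standard))
    stop("no feature is flagged as an internal standard; flag one by ",
         "setting `is_internal_standard` in met_dataset() or via the ",
         "feature-metadata sidecar / `is_prefix` of read_dataset()",
         call. = FALSE)
  is_idx <- which(d$is_internal_standard)
  an_idx <- which(!d$is_internal_standard)
  list(analytes = .subset_dataset(d, features = an_idx),
       standards = .subset_dataset(d, features = is_idx))
}
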
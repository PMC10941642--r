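#' Read a wide-table metabolomics dataset
#'
#' Reads the package's CSV/TSV exchange format: one row per sample, first
#' column the sample id, then the reserved metadata columns `group`,
#' `sample_type` (optional, default `"sample"`) and `replicate` (optional),
#' followed by numeric feature columns.  Lines starting with `#` are
#' comments; the writer emits `# unit_tag: <tag>` and
#' `# is_features: <id>,<id>` headers which are honoured on read.  Empty
#' cells and the literal `NA` are parsed as missing; zero is a measured
#' value.
#'
#' Internal standards can be flagged three ways (in order of precedence):
#' a `# is_features:` comment header, a sidecar feature-metadata CSV with
#' columns `feature_id` and `is_internal_standard`, or a feature-name
#' prefix (`is_prefix`, e.g. `"IS_"`).
#'
#' @param path Path to the CSV/TSV file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param feature_meta Optional path to the sidecar feature-metadata CSV.
#' @param is_prefix Optional feature-name prefix marking internal
#'   standards.
#' @return A [met_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, sep = ",", feature_meta = NULL,
                         is_prefix = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  comment <- grepl("^\\s*#", lines)
  unit_tag <- "area"
  is_features <- NULL
  for (cl in lines[comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*unit_tag:\\s*(.*)$", cl))[[1]]
    if (length(m) == 2) unit_tag <- trimws(m[2])
    m <- regmatches(cl, regexec("^\\s*#\\s*is_features:\\s*(.*)$", cl))[[1]]
    if (length(m) == 2 && nzchar(trimws(m[2])))
      is_features <- trimws(strsplit(m[2], ",")[[1]])
  }
  body <- lines[!comment & nzchar(trimws(lines))]
  if (!length(body)) stop("no header line in ", path, call. = FALSE)
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))

  sample_ids <- df[[1]]
  meta_names <- intersect(c("group", "sample_type", "replicate"),
                          names(df))
  if (!("group" %in% names(df)))
    stop("required column 'group' is missing from ", path, call. = FALSE)
  other <- names(df)[-1]
  feat_idx <- which(!(other %in% meta_names)) + 1L
  feat_cols <- names(df)[feat_idx]
  .check_unique(sample_ids, "sample")
  .check_unique(feat_cols, "feature")

  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(sample_ids, feat_cols))
  for (j in seq_along(feat_cols)) {
    raw <- trimws(df[[feat_idx[j]]])
    miss <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf(
        "non-numeric value '%s' in feature column '%s', row %d (sample '%s')",
        raw[bad[1]], feat_cols[j], bad[1], sample_ids[bad[1]]),
        call. = FALSE)
    num[miss] <- NA_real_
    vals[, j] <- num
  }

  is_flag <- rep(FALSE, length(feat_cols))
  if (!is.null(is_features)) {
    unknown <- setdiff(is_features, feat_cols)
    if (length(unknown))
      stop("is_features header names unknown features: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    is_flag <- feat_cols %in% is_features
  } else if (!is.null(feature_meta)) {
    fm <- utils::read.csv(feature_meta, stringsAsFactors = FALSE)
    if (!all(c("feature_id", "is_internal_standard") %in% names(fm)))
      stop("feature_meta must have columns feature_id, is_internal_standard",
           call. = FALSE)
    is_flag <- feat_cols %in%
      fm$feature_id[as.logical(fm$is_internal_standard)]
  } else if (!is.null(is_prefix)) {
    is_flag <- startsWith(feat_cols, is_prefix)
  }

  met_dataset(vals, group = df$group,
              sample_type = if ("sample_type" %in% names(df))
                df$sample_type else "sample",
              replicate = if ("replicate" %in% names(df)) df$replicate,
              is_internal_standard = is_flag,
              sample_ids = sample_ids, feature_ids = feat_cols,
              unit_tag = unit_tag)
}

#' Write a dataset in the wide-table exchange format
#'
#' Emits the same CSV dialect [read_dataset()] accepts.  Missing values are
#' written as empty cells; the unit tag and internal-standard flags are
#' stored in `#`-comment header lines so that `read_dataset(write_dataset(d))`
#' is lossless.
#'
#' @param d A [met_dataset()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, sep = ",") {
  stopifnot(inherits(d, "met_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(paste0("# unit_tag: ", d$unit_tag), con)
  if (any(d$is_internal_standard))
    writeLines(paste0("# is_features: ",
                      paste(d$feature_ids[d$is_internal_standard],
                            collapse = ",")), con)
  meta <- data.frame(sample_id = d$sample_ids, group = d$group,
                     sample_type = d$sample_type,
                     stringsAsFactors = FALSE)
  if (!is.null(d$replicate)) meta$replicate <- d$replicate
  vals <- d$values
  # full precision so the round trip is bit-exact
  txt <- apply(vals, 2, function(col)
    ifelse(is.na(col), "", sprintf("%.17g", col)))
  if (nrow(vals) == 0)
    txt <- matrix(character(0), 0, ncol(vals),
                  dimnames = list(NULL, colnames(vals)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(vals))
  out <- cbind(as.matrix(meta), txt)
  colnames(out) <- c(names(meta), d$feature_ids)
  writeLines(paste(colnames(out), collapse = sep), con)
  if (nrow(out))
    writeLines(apply(out, 1, paste, collapse = sep), con)
  invisible(path)
}
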
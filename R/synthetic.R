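#' Simulation design for paired concentration/peak-area data
#'
#' Describes the generative world for [simulate_pair()]: a log-normal
#' concentration model with group structure, a shared multiplicative
#' sample-specific error carried by both analytes and internal standards
#' in the peak-area channel, optional leakage of group information into
#' the ISs, replicate injections, pooled QC samples and below-LOD
#' truncation.
#'
#' @param samples_per_group Integer vector of biological subjects per
#'   group; its length sets the number of groups.
#' @param n_features Number of analyte metabolites.
#' @param n_dominant Number of highly abundant, strongly group-separating
#'   features (placed first).
#' @param dominant_fold Fold elevation of the dominant features' baseline.
#' @param n_is Number of internal standards (appended as features
#'   `IS_1..`).
#' @param sigma_e SD of the shared log-normal sample error `e_i` in the
#'   area channel.
#' @param sigma_analyte SD of per-cell log-normal biological noise in the
#'   concentration channel.
#' @param sigma_tech SD of per-cell technical noise in the area channel;
#'   `NULL` (default) uses `sigma_analyte / 2`, so a noise-free design
#'   (`sigma_e = sigma_analyte = 0`) yields `area == conc` exactly.
#' @param beta_group SD of per-(group, feature) effects for ordinary
#'   features.
#' @param dominant_beta SD of group effects for dominant features.
#' @param is_group_leak Coefficient coupling a per-group contrast into the
#'   log IS responses (0 = clean ISs).
#' @param lod_quantile Per-feature quantile of the area channel below
#'   which values are censored to missing; 0 disables censoring.
#' @param absent_blocks Optional data frame with columns `feature`
#'   (index) and `group` (index): blocks whose true concentration is
#'   pushed far below the rest so LOD censoring makes them structurally
#'   missing.
#' @param n_qc Number of pooled QC injections.
#' @param replicates Injection replicates per biological subject.
#' @param base_log_mean,base_log_sd Baseline log-concentration level and
#'   spread across features.
#' @param seed Integer seed; the pair is bit-reproducible given the seed.
#' @return A `sim_design` list.
#' @export
sim_design <- function(samples_per_group = c(10, 10),
                       n_features = 10,
                       n_dominant = 0,
                       dominant_fold = 50,
                       n_is = 1,
                       sigma_e = 0.3,
                       sigma_analyte = 0.2,
                       sigma_tech = NULL,
                       beta_group = 0.4,
                       dominant_beta = 1.5,
                       is_group_leak = 0,
                       lod_quantile = 0,
                       absent_blocks = NULL,
                       n_qc = 0,
                       replicates = 1,
                       base_log_mean = log(100),
                       base_log_sd = 1,
                       seed = 1L) {
  d <- list(samples_per_group = as.integer(samples_per_group),
            n_groups = length(samples_per_group),
            n_features = as.integer(n_features),
            n_dominant = as.integer(n_dominant),
            dominant_fold = dominant_fold,
            n_is = as.integer(n_is),
            sigma_e = sigma_e, sigma_analyte = sigma_analyte,
            sigma_tech = if (is.null(sigma_tech)) sigma_analyte / 2
                         else sigma_tech,
            beta_group = beta_group, dominant_beta = dominant_beta,
            is_group_leak = is_group_leak,
            lod_quantile = lod_quantile,
            absent_blocks = absent_blocks,
            n_qc = as.integer(n_qc),
            replicates = as.integer(replicates),
            base_log_mean = base_log_mean, base_log_sd = base_log_sd,
            seed = as.integer(seed))
  if (any(d$samples_per_group < 1) || d$n_features < 1 || d$n_is < 0 ||
      d$replicates < 1 || d$n_qc < 0)
    stop("invalid design: counts must be positive", call. = FALSE)
  if (d$sigma_e < 0 || d$sigma_analyte < 0 || d$sigma_tech < 0)
    stop("invalid design: sigmas must be non-negative", call. = FALSE)
  if (d$lod_quantile < 0 || d$lod_quantile >= 1)
    stop("invalid design: lod_quantile must be in [0, 1)", call. = FALSE)
  if (d$n_dominant > d$n_features)
    stop("invalid design: n_dominant > n_features", call. = FALSE)
  class(d) <- "sim_design"
  d
}

#' Study-like simulation presets
#'
#' `"milk"`: a well-controlled food study — 4 groups of 13/6/7/3
#' biological samples analysed in triplicate, 10 pooled QC injections,
#' 16 metabolites of which 2 are dominant (50-fold elevated) and strongly
#' group-separating, 1 internal standard, and structural below-LOD
#' missingness of a few metabolites in the last (almond-like) group.
#'
#' `"urine"`: a clinical cohort — 2 groups of 53/63 subjects, single
#' injections, 8 metabolites, 1 internal standard, large inter-individual
#' variance and a weak group effect.
#'
#' @param name `"milk"` or `"urine"`.
#' @param seed Seed stored in the design.
#' @return A [sim_design()].
#' @export
sim_preset <- function(name = c("milk", "urine"), seed = 1L) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: milk, urine",
         call. = FALSE))
  switch(name,
    milk = sim_design(
      samples_per_group = c(13, 6, 7, 3),
      n_features = 16, n_dominant = 2, dominant_fold = 50,
      n_is = 1, sigma_e = 0.3, sigma_analyte = 0.2,
      beta_group = 0.4, dominant_beta = 1.5, is_group_leak = 0,
      lod_quantile = 0.05,
      absent_blocks = data.frame(feature = c(3, 4, 5),
                                 group = c(4, 4, 4)),
      n_qc = 10, replicates = 3, seed = seed),
    urine = sim_design(
      samples_per_group = c(53, 63),
      n_features = 8, n_dominant = 1, dominant_fold = 10,
      n_is = 1, sigma_e = 0.3, sigma_analyte = 0.8,
      beta_group = 0.15, dominant_beta = 0.3, is_group_leak = 0,
      lod_quantile = 0, n_qc = 0, replicates = 1, seed = seed))
}

#' Simulate a paired concentration/peak-area dataset
#'
#' Draws true concentrations `c[i, j] = exp(mu_gj + eps_ij)` from a
#' log-normal group model (dominant features get an elevated baseline and
#' stronger group effects), then produces the semiquantitative channel as
#' `a[i, j] = c[i, j] * e_i * exp(tech_ij)` where `e_i ~
#' LogNormal(0, sigma_e)` is the shared sample-specific error, carried
#' identically by the internal standards.  Replicate injections share the
#' subject-level concentration; QC samples are drawn around the grand
#' mean.  Optionally, cells below the per-feature `lod_quantile` of the
#' area channel are censored to missing, and `absent_blocks` force
#' structural missingness of whole (feature, group) blocks.
#'
#' @param design A [sim_design()] or preset name.
#' @return A list with `conc` (analytes only, complete), `area` (analytes
#'   plus IS columns, possibly with censored cells) and `truth` (list with
#'   `log_e` per sample, `mu` group-by-feature log means, `gamma` the
#'   group contrast leaked into the ISs, and the design).
#' @export
simulate_pair <- function(design) {
  if (is.character(design)) design <- sim_preset(design)
  stopifnot(inherits(design, "sim_design"))
  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(design$seed)

  G <- design$n_groups
  p <- design$n_features
  reps <- design$replicates

  feat_ids <- sprintf("met_%02d", seq_len(p))
  is_ids <- if (design$n_is > 0) sprintf("IS_%d", seq_len(design$n_is))

  # per-feature baselines; dominant features elevated and listed first.
  # Dominance is anchored to the largest ordinary baseline so the stated
  # fold elevation holds regardless of the baseline draw.
  base <- stats::rnorm(p, design$base_log_mean, design$base_log_sd)
  dom <- seq_len(design$n_dominant)
  if (design$n_dominant > 0 && design$n_dominant < p)
    base[dom] <- max(base[-dom]) + log(design$dominant_fold) +
      stats::rnorm(design$n_dominant, 0, 0.2)
  else if (design$n_dominant > 0)
    base[dom] <- base[dom] + log(design$dominant_fold)

  # per-(group, feature) effects
  beta <- matrix(stats::rnorm(G * p, 0, design$beta_group), G, p)
  if (design$n_dominant > 0)
    beta[, dom] <- matrix(stats::rnorm(G * design$n_dominant, 0,
                                       design$dominant_beta),
                          G, design$n_dominant)
  mu <- sweep(beta, 2, base, `+`)
  if (!is.null(design$absent_blocks)) {
    for (k in seq_len(nrow(design$absent_blocks))) {
      fb <- design$absent_blocks$feature[k]
      gb <- design$absent_blocks$group[k]
      mu[gb, fb] <- mu[gb, fb] - log(1e4)  # far below everything else
    }
  }

  n_subj <- sum(design$samples_per_group)
  subj_group <- rep(seq_len(G), design$samples_per_group)
  # subject-level log concentrations
  log_c_subj <- mu[subj_group, , drop = FALSE] +
    matrix(stats::rnorm(n_subj * p, 0, design$sigma_analyte), n_subj, p)

  # expand to replicate injections
  inj_subj <- rep(seq_len(n_subj), each = reps)
  log_c <- log_c_subj[inj_subj, , drop = FALSE]
  if (reps > 1)  # small technical spread between injections, conc channel
    log_c <- log_c + matrix(stats::rnorm(length(log_c), 0,
                                         design$sigma_tech), nrow(log_c))

  # QC injections around the grand mean
  n_qc <- design$n_qc
  if (n_qc > 0) {
    qc_mu <- colMeans(mu)
    log_c_qc <- matrix(qc_mu, n_qc, p, byrow = TRUE) +
      matrix(stats::rnorm(n_qc * p, 0, 0.05), n_qc, p)
    log_c <- rbind(log_c, log_c_qc)
  }
  n <- nrow(log_c)
  conc_vals <- exp(log_c)

  group <- c(paste0("G", subj_group[inj_subj]), rep("QC", n_qc))
  sample_type <- c(rep("sample", length(inj_subj)), rep("qc", n_qc))
  replicate <- c(paste0("S", inj_subj, "_r",
                        stats::ave(inj_subj, inj_subj,
                                   FUN = seq_along)),
                 if (n_qc > 0) paste0("QC_r", seq_len(n_qc)))
  ids <- sprintf("inj_%03d", seq_len(n))

  # shared multiplicative sample error (area channel only)
  log_e <- stats::rnorm(n, 0, design$sigma_e)
  area_vals <- conc_vals * exp(log_e) *
    exp(matrix(stats::rnorm(n * p, 0, design$sigma_tech), n, p))

  # internal standards: constant spike times the shared error
  gamma <- stats::rnorm(G)
  gamma_i <- c(gamma[subj_group[inj_subj]], rep(0, n_qc))
  if (design$n_is > 0) {
    is_base <- exp(stats::rnorm(design$n_is, design$base_log_mean, 0.1))
    is_vals <- sapply(seq_len(design$n_is), function(k)
      is_base[k] * exp(log_e + design$is_group_leak * gamma_i +
                         stats::rnorm(n, 0, 0.02)))
    is_vals <- matrix(is_vals, n, design$n_is)
    colnames(is_vals) <- is_ids
  } else is_vals <- NULL

  # below-LOD censoring on the area channel
  if (design$lod_quantile > 0) {
    for (j in seq_len(p)) {
      lod <- stats::quantile(area_vals[, j], design$lod_quantile)
      area_vals[area_vals[, j] <= lod, j] <- NA
    }
  }

  conc <- met_dataset(conc_vals, group = group,
                      sample_type = sample_type, replicate = replicate,
                      is_internal_standard = FALSE,
                      sample_ids = ids, feature_ids = feat_ids,
                      unit_tag = "concentration")
  area <- met_dataset(cbind(area_vals, is_vals), group = group,
                      sample_type = sample_type, replicate = replicate,
                      is_internal_standard = c(rep(FALSE, p),
                                               rep(TRUE, design$n_is)),
                      sample_ids = ids,
                      feature_ids = c(feat_ids, is_ids),
                      unit_tag = "area")
  list(conc = conc, area = area,
       truth = list(log_e = stats::setNames(log_e, ids), mu = mu,
                    gamma = gamma, design = design))
}
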
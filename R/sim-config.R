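#' Configuration for the synthetic multimodal cohort generator
#'
#' Defaults emulate the study conditions of a late-stage high-grade serous
#' ovarian cancer cohort: 444 patients of whom 40 form a held-out test set;
#' a 600-dimensional radiomic-like block and a 216-dimensional
#' histopathology-like block with a few planted prognostic features,
#' correlated decoy blocks and a fraction of near-constant features;
#' per-modality missingness at the observed availability rates (omental CT
#' 251/404, H&E 243/404, known HRD status 337/404 of the training pool);
#' right-censored overall and progression-free survival under proportional
#' hazards with roughly one third of OS records censored; a binary HRD label
#' with a protective effect for deficient tumors; and a 3-level ordinal
#' chemotherapy response score (CRS) shifted by the true risk.
#'
#' @param n_patients Number of patients to simulate.
#' @param n_features Named integer vector: features per modality.
#' @param planted Tibble with columns `modality`, `index`, `log_hr`; the
#'   planted prognostic features entering the true linear predictor.
#' @param decoy_block_correlation Equicorrelation within decoy blocks, in
#'   `[0, 1)`; exercises the multicollinearity pruning of the selection
#'   cascade.
#' @param decoy_block_size Number of features per equicorrelated decoy block.
#' @param near_constant_fraction Fraction of each modality's features that
#'   are near-constant (scaled IQR < 0.1 by construction), so the IQR filter
#'   has work to do. The default 0.26 reduces a 600-feature block to
#'   approximately 444 survivors.
#' @param availability Named probabilities that a patient has each feature
#'   modality measured.
#' @param baseline Baseline hazard: `list(family = "weibull", shape, scale)`.
#'   Shape 1 is the exponential special case. Scale is in months.
#' @param pfs_scale Weibull scale (months) for the PFS endpoint.
#' @param censoring_rate_target Target fraction of censored OS/PFS records;
#'   an independent exponential censoring rate is solved by root finding.
#' @param hrd_prevalence Probability a patient's tumor is truly HRD.
#' @param hrd_known_prob Probability the HRD label is observed (otherwise the
#'   call is `"ambiguous"`).
#' @param hrd_log_hr Log hazard ratio of true HRD status (negative =
#'   protective).
#' @param clinical_log_hr Named vector of log hazard ratios for the planted
#'   clinical effects `rd` (residual disease <= 1 cm) and `parpi` (PARP
#'   inhibitor receipt).
#' @param cross_modality_correlation Correlation between planted features of
#'   different modalities via a shared patient-level factor, in `[0, 1)`.
#' @param crs_cutpoints Two latent-scale cutpoints for the ordinal CRS.
#' @param crs_known_prob Probability the CRS label is observed.
#' @param seed Integer seed; a fixed seed yields a byte-identical cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 444,
                       n_features = c(radiomic = 600L, histopathology = 216L),
                       planted = default_planted(),
                       decoy_block_correlation = 0.5,
                       decoy_block_size = 10L,
                       near_constant_fraction = 0.26,
                       availability = c(radiomic = 251 / 404, histopathology = 243 / 404),
                       baseline = list(family = "weibull", shape = 1, scale = 60),
                       pfs_scale = 18,
                       censoring_rate_target = 132 / 404,
                       hrd_prevalence = 119 / 337,
                       hrd_known_prob = 337 / 404,
                       hrd_log_hr = -0.45,
                       clinical_log_hr = c(rd = -0.25, parpi = -0.15),
                       cross_modality_correlation = 0,
                       crs_cutpoints = c(-1, 1),
                       crs_known_prob = 0.15,
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) abort("`n_patients` must be positive")
  if (is.null(names(n_features)) || any(!nzchar(names(n_features)))) {
    abort("`n_features` must be a named vector of per-modality counts")
  }
  planted <- as_tibble(planted)
  stopifnot(all(c("modality", "index", "log_hr") %in% names(planted)))
  for (i in seq_len(nrow(planted))) {
    m <- planted$modality[i]
    if (!m %in% names(n_features)) {
      abort(sprintf("planted feature modality '%s' not in `n_features`", m))
    }
    if (planted$index[i] < 1 || planted$index[i] > n_features[[m]]) {
      abort(sprintf("planted feature index %d out of range for modality '%s'",
                    planted$index[i], m))
    }
  }
  probs <- c(availability, censoring_rate_target, hrd_prevalence,
             hrd_known_prob, crs_known_prob, near_constant_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (decoy_block_correlation < 0 || decoy_block_correlation >= 1) {
    abort("`decoy_block_correlation` must be in [0, 1)")
  }
  if (cross_modality_correlation < 0 || cross_modality_correlation >= 1) {
    abort("`cross_modality_correlation` must be in [0, 1)")
  }
  stopifnot(baseline$family == "weibull", baseline$shape > 0, baseline$scale > 0)

  structure(
    list(
      n_patients = as.integer(n_patients),
      n_features = n_features,
      planted = planted,
      decoy_block_correlation = decoy_block_correlation,
      decoy_block_size = as.integer(decoy_block_size),
      near_constant_fraction = near_constant_fraction,
      availability = availability,
      baseline = baseline,
      pfs_scale = pfs_scale,
      censoring_rate_target = censoring_rate_target,
      hrd_prevalence = hrd_prevalence,
      hrd_known_prob = hrd_known_prob,
      hrd_log_hr = hrd_log_hr,
      clinical_log_hr = clinical_log_hr,
      cross_modality_correlation = cross_modality_correlation,
      crs_cutpoints = crs_cutpoints,
      crs_known_prob = crs_known_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default planted prognostic effects
#'
#' One radiomic feature at log HR 0.5 (mirroring a single-texture-feature
#' imaging signature) and two independent histopathology features at log HR
#' 0.3 each (mirroring a two-feature morphometric signature).
#'
#' @return A tibble with columns `modality`, `index`, `log_hr`.
#' @export
default_planted <- function() {
  tibble(
    modality = c("radiomic", "histopathology", "histopathology"),
    index = c(1L, 1L, 2L),
    log_hr = c(0.5, 0.3, 0.3)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  features:", paste(sprintf("%s=%d", names(x$n_features), x$n_features),
                           collapse = ", "), "\n")
  cat("  planted effects:", nrow(x$planted), " censoring target:",
      round(x$censoring_rate_target, 3), "\n")
  invisible(x)
}
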
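# Late fusion: a second-stage Cox model over per-modality risk columns,
# trained on the intersection set while each submodel learns from all of
# its available unimodal cases.
#
# Orientation convention: the assembled score table is RISK-oriented --
# fitted submodels contribute their log partial hazard (higher = worse) and
# the genomic column is the rule-based risk (HRP = 1, HRD = 0, ambiguous =
# missing) -- so informative modalities receive positive second-stage
# coefficients. Predictions then revert to the package-wide protective
# convention (negative log partial hazard, higher = better).

#' Assemble the per-patient, per-modality score table
#'
#' One row per patient, one column per modality, risk-oriented (see above).
#' Missing entries are preserved: a patient without a modality, or with an
#' ambiguous HRD call, has `NA` in that column.
#'
#' @param cohort An `mm_cohort`.
#' @param submodels Named list of `cox_submodel`s (names are modalities);
#'   the clinical submodel, if present, is applied to the encoded manifest.
#' @param clinical Optional pre-encoded clinical matrix (defaults to
#'   [encode_clinical()] on the manifest -- supply the training-encoded
#'   version to freeze the age range).
#' @return A tibble: `id` plus one numeric column per available modality
#'   (including `genomic` from the manifest HRD calls).
#' @export
assemble_submodel_scores <- function(cohort, submodels, clinical = NULL) {
  stopifnot(inherits(cohort, "mm_cohort"))
  manifest <- cohort$manifest
  out <- tibble(id = manifest$id)

  if ("hrd_call" %in% names(manifest)) {
    out$genomic <- genomic_risk(manifest$hrd_call)
  }
  for (m in names(submodels)) {
    model <- submodels[[m]]
    data_m <- if (m == "clinical") {
      clinical %||% encode_clinical(manifest)
    } else {
      cohort$features[[m]]
    }
    if (is.null(data_m)) abort(paste0("no feature data for modality: ", m))
    scores <- predict_risk(model, data_m)
    # risk orientation for fusion: log partial hazard
    out <- left_join(out, tibble(id = scores$id, v = -scores$score), by = "id")
    names(out)[names(out) == "v"] <- m
  }
  out
}

#' Fit the second-stage fusion Cox model
#'
#' An L2-penalized Cox model (default strength 0.5) on the modality score
#' columns, fitted over the intersection set only: patients with every
#' included modality present. The inputs are not re-standardized -- they
#' are already on the log-hazard scale -- and the stage fits exactly one
#' coefficient per modality.
#'
#' @param scores Score table from [assemble_submodel_scores()].
#' @param outcomes Outcomes tibble (`id`, `time`, `event`).
#' @param modalities Modalities to include.
#' @param l2 L2 penalty strength.
#' @return A `fusion_model`.
#' @export
fit_fusion <- function(scores, outcomes, modalities, l2 = 0.5) {
  check_outcomes(outcomes)
  missing_cols <- setdiff(modalities, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("score table lacks modalities: ",
                 paste(missing_cols, collapse = ", ")))
  }
  joined <- inner_join(scores[, c("id", modalities), drop = FALSE], outcomes,
                       by = "id")
  complete <- stats::complete.cases(joined[, modalities, drop = FALSE])
  if (!any(complete)) {
    per_mod <- map_dbl(modalities, ~ sum(!is.na(joined[[.x]])))
    abort(sprintf("empty intersection set; binding modality: %s",
                  modalities[which.min(per_mod)]))
  }
  joined <- joined[complete, , drop = FALSE]
  if (sum(joined$event) < 2) abort("intersection set has fewer than 2 events")

  X <- as.matrix(joined[, modalities, drop = FALSE])
  fit <- fit_cox_penalized(X, joined$time, joined$event, l2 = l2)
  structure(
    list(modalities = modalities, coef = fit$coef, se = fit$se, l2 = l2,
         n_intersection = nrow(joined), n_events = fit$n_events),
    class = "fusion_model"
  )
}

#' Predict fused risk scores
#'
#' The fused score is the negative log partial hazard of the second-stage
#' model; patients missing any included modality get a missing score.
#'
#' @param model A `fusion_model`.
#' @param scores Score table from [assemble_submodel_scores()].
#' @return A tibble (`id`, `score`).
#' @export
predict_fused <- function(model, scores) {
  stopifnot(inherits(model, "fusion_model"))
  X <- as.matrix(scores[, model$modalities, drop = FALSE])
  lp <- as.vector(X %*% model$coef)
  tibble(id = scores$id, score = -lp)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s: fitted on %d intersection patients (%d events)\n",
              combo_label(x$modalities), x$n_intersection, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.fusion_model <- function(x, ...) {
  tibble(
    term = x$modalities,
    estimate = unname(x$coef),
    std.error = unname(x$se),
    statistic = unname(x$coef / x$se),
    p.value = 2 * pnorm(-abs(unname(x$coef / x$se)))
  )
}

#' @export
glance.fusion_model <- function(x, ...) {
  tibble(combo = combo_label(x$modalities),
         n_intersection = x$n_intersection, n_events = x$n_events,
         l2 = x$l2)
}
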
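# The feature-selection cascade: univariate Cox screening with a fallback
# ladder -> scaled-IQR filter -> Benjamini-Hochberg (largest feature spaces
# only) -> greedy multivariable pruning.

#' Configuration of the selection cascade
#'
#' @param iqr_threshold Minimum scaled IQR (IQR of the min-max scaled
#'   feature) a feature must reach to survive filtering.
#' @param alpha Significance level for both the univariate screen and the
#'   multivariable pruning pass ("significant with 95% confidence").
#' @param fallback_l2 L2 strength for the refit attempted when an
#'   unregularized univariate fit fails to converge.
#' @param apply_bh Apply Benjamini-Hochberg correction at level `alpha`
#'   to the univariate p-values (used for the largest feature space,
#'   radiomics).
#' @param control_covariate Optional feature name included in every
#'   univariate model as a nuisance covariate (e.g. relative specimen size
#'   for histopathology); it is never itself a candidate.
#' @param min_events Minimum number of observed events required to run the
#'   cascade at all.
#' @return A `selection_config` list.
#' @export
selection_config <- function(iqr_threshold = 0.1, alpha = 0.05,
                             fallback_l2 = 0.2, apply_bh = FALSE,
                             control_covariate = NULL, min_events = 10L) {
  stopifnot(iqr_threshold > 0, iqr_threshold < 1, alpha > 0, alpha < 1,
            fallback_l2 >= 0)
  structure(
    list(iqr_threshold = iqr_threshold, alpha = alpha,
         fallback_l2 = fallback_l2, apply_bh = apply_bh,
         control_covariate = control_covariate,
         min_events = as.integer(min_events)),
    class = "selection_config"
  )
}

#' Scaled interquartile range of a feature
#'
#' The feature is min-max scaled to `[0, 1]` and the IQR of the scaled
#' values is returned (linear-interpolation quantiles). A constant feature
#' has scaled IQR 0 by definition.
#'
#' @param x Numeric vector.
#' @return A scalar in `[0, 1]`.
#' @export
scaled_iqr <- function(x) {
  r <- range(x)
  if (!all(is.finite(r)) || r[1] == r[2]) return(0)
  s <- (x - r[1]) / (r[2] - r[1])
  diff(q_linear(s, c(0.25, 0.75)))
}

#' Filter low-variation features by scaled IQR
#'
#' Applied to training rows only; the min-max scaling parameters and the
#' verdict per feature are recorded in the `"scaling"` attribute for
#' test-time reuse.
#'
#' @param data Feature matrix tibble: `id` column plus numeric features.
#' @param threshold Minimum scaled IQR to retain a feature.
#' @return The filtered tibble, with a `"scaling"` attribute.
#' @export
scaled_iqr_filter <- function(data, threshold = 0.1) {
  feats <- feature_cols(data)
  scaling <- map(feats, function(f) {
    x <- data[[f]]
    r <- range(x)
    tibble(feature = f, min = r[1], max = r[2], scaled_iqr = scaled_iqr(x))
  })
  scaling <- bind_rows(scaling)
  scaling$kept <- scaling$scaled_iqr >= threshold
  out <- data[, c("id", scaling$feature[scaling$kept]), drop = FALSE]
  attr(out, "scaling") <- scaling
  out
}

#' Univariate Cox screen of one feature
#'
#' Fits an unregularized Cox proportional hazards model of the outcome on
#' one feature (optionally bivariate with a control covariate). On
#' convergence failure the fit is re-attempted with L2 strength
#' `fallback_l2`; if that also fails the feature is assigned log HR 0 and
#' p-value 1 with status `"failed-defaulted"`.
#'
#' @param x Feature values.
#' @param time,event Outcome vectors (months; `TRUE` = event observed).
#' @param control Optional control covariate values.
#' @param config A [selection_config()].
#' @param feature Feature name for the output row.
#' @return A one-row tibble: feature, log_hr, ci_lo, ci_hi, p, status.
#' @export
univariate_cox <- function(x, time, event, control = NULL,
                           config = selection_config(), feature = "x") {
  if (sum(event) < 2) abort("need at least 2 events for a univariate fit")
  res <- cox_ladder(x, time, event, control = control,
                    fallback_l2 = config$fallback_l2)
  tibble(feature = feature, log_hr = res$log_hr, ci_lo = res$ci_lo,
         ci_hi = res$ci_hi, p = res$p, status = res$status)
}

#' Univariate Cox screen of every feature in a matrix
#'
#' @param data Feature matrix tibble (`id` + features).
#' @param outcomes Outcomes tibble (`id`, `time`, `event`); joined by id.
#' @param config A [selection_config()]; if `control_covariate` is set,
#'   that column is used as the nuisance covariate and excluded from the
#'   candidates.
#' @return A tibble with one row per screened feature.
#' @export
univariate_cox_scan <- function(data, outcomes, config = selection_config()) {
  check_outcomes(outcomes)
  joined <- inner_join(data, outcomes, by = "id")
  ctrl_name <- config$control_covariate
  ctrl <- if (!is.null(ctrl_name)) {
    if (!ctrl_name %in% names(joined)) {
      abort(sprintf("control covariate '%s' not in the feature matrix", ctrl_name))
    }
    joined[[ctrl_name]]
  }
  feats <- setdiff(feature_cols(data), ctrl_name)
  bind_rows(map(feats, function(f) {
    univariate_cox(joined[[f]], joined$time, joined$event,
                   control = ctrl, config = config, feature = f)
  }))
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up procedure controlling the false discovery rate at level `q`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector of rejections (empty input gives empty output).
#' @export
bh_reject <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH") <= q
}

#' Greedy multivariable pruning of ordered candidates
#'
#' Forward pass over candidates ordered by ascending univariate p-value:
#' the candidate is tentatively appended to the current signature, the
#' multivariable Cox model is refitted, and the candidate is kept only when
#' the Wald p-value of the newly added covariate is below `alpha`
#' (otherwise the next candidate overwrites its slot). A multivariable fit
#' that fails both ladder rungs rejects the candidate and is logged in the
#' `"fit_failures"` attribute. This yields signatures with low
#' multicollinearity: a near-copy of an accepted feature cannot be
#' significant given the original.
#'
#' @param candidates Tibble with columns `feature` and `p`, unique features
#'   ordered by ascending p (ties broken lexicographically by name).
#' @param data Feature matrix tibble containing the candidate columns.
#' @param outcomes Outcomes tibble (`id`, `time`, `event`).
#' @param alpha Significance level for acceptance.
#' @param fallback_l2 L2 strength of the fallback rung.
#' @return An `mm_signature`: tibble of kept features with their
#'   multivariable log HR and p at acceptance time.
#' @export
algorithm1_select <- function(candidates, data, outcomes, alpha = 0.05,
                              fallback_l2 = 0.2) {
  check_outcomes(outcomes)
  stopifnot(!anyDuplicated(candidates$feature))
  joined <- inner_join(data, outcomes, by = "id")
  time <- joined$time; event <- joined$event

  kept <- character(0)
  accept_log_hr <- numeric(0)
  accept_p <- numeric(0)
  failures <- character(0)

  for (f in candidates$feature) {
    trial <- c(kept, f)
    fit <- cox_multi_ladder(as.matrix(joined[, trial, drop = FALSE]),
                            time, event, fallback_l2 = fallback_l2)
    if (is.null(fit)) {
      failures <- c(failures, f)
      next
    }
    j <- length(trial)
    p_new <- 2 * pnorm(-abs(fit$coef[j] / fit$se[j]))
    if (is.finite(p_new) && p_new < alpha) {
      kept <- trial
      accept_log_hr <- c(accept_log_hr, fit$coef[j])
      accept_p <- c(accept_p, p_new)
    }
  }

  out <- tibble(feature = kept, log_hr = accept_log_hr, p = accept_p)
  class(out) <- c("mm_signature", class(out))
  attr(out, "fit_failures") <- failures
  out
}

#' Run the full selection cascade for one modality
#'
#' Composes, in order: the univariate Cox screen of every feature (with the
#' fallback ladder, and the control covariate if configured), the
#' scaled-IQR filter, Benjamini-Hochberg correction when configured (the
#' largest feature space) or the raw `alpha` threshold otherwise, ordering
#' of the surviving features by p-value, and the greedy multivariable
#' pruning pass. Stage-by-stage candidate counts are recorded in the
#' `"audit"` attribute.
#'
#' @param data Training feature matrix tibble (`id` + features).
#' @param outcomes Training outcomes tibble (`id`, `time`, `event`).
#' @param config A [selection_config()].
#' @return An `mm_signature` (possibly empty) with `"audit"`,
#'   `"univariate"` and `"scaling"` attributes.
#' @export
select_modality <- function(data, outcomes, config = selection_config()) {
  check_outcomes(outcomes)
  joined_ids <- intersect(data$id, outcomes$id)
  n_events <- sum(outcomes$event[outcomes$id %in% joined_ids])
  if (n_events < config$min_events) {
    abort(sprintf(
      "only %d events among %d patients; at least %d required for selection",
      n_events, length(joined_ids), config$min_events))
  }

  uni <- univariate_cox_scan(data, outcomes, config)
  filtered <- scaled_iqr_filter(
    data[, setdiff(names(data), config$control_covariate), drop = FALSE],
    threshold = config$iqr_threshold
  )
  scaling <- attr(filtered, "scaling")
  uni_kept <- uni[uni$feature %in% feature_cols(filtered), , drop = FALSE]

  if (config$apply_bh) {
    sig <- uni_kept[bh_reject(uni_kept$p, q = config$alpha), , drop = FALSE]
  } else {
    sig <- uni_kept[uni_kept$p < config$alpha, , drop = FALSE]
  }
  # deterministic candidate order: ascending p, ties by feature name
  sig <- sig[order(sig$p, sig$feature), , drop = FALSE]

  selected <- algorithm1_select(sig, data, outcomes, alpha = config$alpha,
                                fallback_l2 = config$fallback_l2)
  if (nrow(selected) == 0) {
    inform("selection cascade returned an empty signature")
  }
  attr(selected, "audit") <- tibble(
    stage = c("input", "univariate", "iqr_filter", "significance", "multivariable"),
    n_in = c(length(feature_cols(data)) - length(config$control_covariate),
             nrow(uni), nrow(uni_kept), nrow(sig), nrow(sig)),
    n_out = c(nrow(uni), nrow(uni_kept), nrow(sig), nrow(sig), nrow(selected))
  )
  attr(selected, "univariate") <- uni
  attr(selected, "scaling") <- scaling
  selected
}

#' @export
print.mm_signature <- function(x, ...) {
  cat("<mm_signature> ", nrow(x), " feature(s)\n", sep = "")
  if (nrow(x) > 0) print(as_tibble(x))
  audit <- attr(x, "audit")
  if (!is.null(audit)) {
    cat("cascade audit:\n")
    print(as_tibble(audit))
  }
  invisible(x)
}
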
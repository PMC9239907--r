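# Clinical encoding, final unimodal Cox submodels with fixed L2, and risk
# prediction as negative log partial hazards.

#' Encode clinical records into a numeric feature matrix
#'
#' Residual disease (RD) status becomes a binary indicator (1 when RD is
#' <= 1 cm, including complete gross resection, else 0); PARP-inhibitor
#' receipt and adnexal-lesion presence are 0/1; age is scaled by the
#' training-set range and clipped to `[0, 1]` at test time; stage and
#' treatment are one-hot encoded including their `"unknown"` categories, so
#' the encoding is total: every record maps to a fixed-length vector.
#'
#' @param data Manifest-like tibble with columns `id`, `rd_status`,
#'   `parpi`, `adnexal_present`, `age`, `stage`, `treatment`.
#' @param age_range Length-2 numeric training age range; computed from
#'   `data` when `NULL` (training-time use).
#' @return A tibble: `id` plus numeric clinical features. The applied age
#'   range is stored in the `"age_range"` attribute.
#' @export
encode_clinical <- function(data, age_range = NULL) {
  if (is.null(age_range)) age_range <- range(data$age)
  span <- diff(age_range)
  age_scaled <- if (span > 0) (data$age - age_range[1]) / span else rep(0, nrow(data))
  age_scaled <- pmin(pmax(age_scaled, 0), 1)

  one_hot <- function(x, levels, prefix) {
    x <- ifelse(x %in% levels, x, "unknown")
    cols <- map(levels, ~ as.numeric(x == .x))
    setNames(cols, paste0(prefix, "_", gsub("[^A-Za-z0-9]+", "_", levels)))
  }

  out <- c(
    list(
      id = data$id,
      rd = as.numeric(data$rd_status == "<=1cm"),
      parpi = as.numeric(data$parpi),
      adnexal = as.numeric(data$adnexal_present),
      age_scaled = age_scaled
    ),
    one_hot(data$stage, c("I", "II", "III", "IV", "unknown"), "stage"),
    one_hot(data$treatment, c("NACT-IDS", "PDS", "unknown"), "treatment")
  )
  res <- as_tibble(out)
  attr(res, "age_range") <- age_range
  res
}

#' Fit a final unimodal Cox submodel
#'
#' Maximizes the Efron partial likelihood penalized by
#' `(l2 / 2) * sum(beta^2)` (default strength 0.5, no L1 term) on the
#' signature features, which are z-scored on the training data first so the
#' penalty acts on a common scale; the scaling is stored and inverted at
#' prediction. Nonconvergence is an error: a final model never silently
#' defaults.
#'
#' @param data Training feature matrix tibble containing the signature
#'   columns.
#' @param outcomes Training outcomes tibble (`id`, `time`, `event`).
#' @param signature An `mm_signature` or character vector of feature names.
#' @param l2 L2 penalty strength.
#' @param modality Modality tag stored in the model.
#' @return A `cox_submodel`.
#' @export
fit_submodel <- function(data, outcomes, signature, l2 = 0.5,
                         modality = "unimodal") {
  check_outcomes(outcomes)
  features <- if (is.data.frame(signature)) signature$feature else signature
  if (length(features) == 0) abort("cannot fit a submodel on an empty signature")
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("features absent from the matrix: ",
                 paste(missing_cols, collapse = ", ")))
  }
  joined <- inner_join(data[, c("id", features), drop = FALSE], outcomes, by = "id")
  if (sum(joined$event) < 2) abort("need at least 2 events to fit a submodel")

  X <- as.matrix(joined[, features, drop = FALSE])
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")

  fit <- fit_cox_penalized(Xs, joined$time, joined$event, l2 = l2)
  structure(
    list(
      modality = modality, features = features,
      coef = fit$coef, se = fit$se,
      center = center, scale = scale_,
      l2 = l2, ties = "efron",
      n = fit$n, n_events = fit$n_events
    ),
    class = "cox_submodel"
  )
}

#' Predict per-patient risk scores from a submodel
#'
#' The score is the negative log partial hazard `-(x' beta)` after applying
#' the stored training standardization, so a higher score means a lower
#' predicted hazard (longer expected survival). Patients with any missing
#' feature value get a missing score.
#'
#' @param model A `cox_submodel`.
#' @param data Feature matrix tibble containing the model's features.
#' @return A tibble (`id`, `score`).
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "cox_submodel"))
  missing_cols <- setdiff(model$features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("feature name mismatch; absent: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[, model$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  lp <- as.vector(Xs %*% model$coef)
  tibble(id = data$id, score = -lp)
}

#' @export
print.cox_submodel <- function(x, ...) {
  cat(sprintf("<cox_submodel> %s: %d feature(s), l2 = %.2g, %d patients (%d events)\n",
              x$modality, length(x$features), x$l2, x$n, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.cox_submodel <- function(x, ...) {
  tibble(
    term = x$features,
    estimate = unname(x$coef),
    std.error = unname(x$se),
    statistic = unname(x$coef / x$se),
    p.value = 2 * pnorm(-abs(unname(x$coef / x$se)))
  )
}

#' @export
glance.cox_submodel <- function(x, ...) {
  tibble(modality = x$modality, n = x$n, n_events = x$n_events,
         n_features = length(x$features), l2 = x$l2, ties = x$ties)
}
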
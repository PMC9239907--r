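# Cox model fitting internals.
#
# All fits use the Efron approximation for tied event times. The penalized
# objective maximized by `fit_cox_penalized()` is
#     logPL(beta) - (l2 / 2) * sum(beta^2),
# i.e. survival::ridge() with scale = FALSE, so the penalty strength is
# interpretable on the scale of the (already standardized) inputs.

cox_control <- function() {
  coxph.control(eps = 1e-11, toler.chol = 1e-13, iter.max = 100)
}

# Fit coxph and capture convergence trouble. Returns list(fit, ok, notes).
# Monotone-likelihood warnings ("coefficient may be infinite"), singularity,
# iteration exhaustion and NA coefficients all count as failures.
cox_try <- function(formula, data, l2 = 0) {
  notes <- character()
  fit <- withCallingHandlers(
    tryCatch(
      coxph(formula, data = data, control = cox_control()),
      error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NULL
      }
    ),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  ok <- !is.null(fit) && all(is.finite(coef(fit))) && length(notes) == 0
  list(fit = fit, ok = ok, notes = notes)
}

# Univariate (optionally bivariate with a control covariate) fit with the
# fallback ladder: unregularized -> L2 (default 0.2) -> defaulted to
# logHR 0 / p 1. Reports the feature's coefficient, Wald CI / p and a
# convergence status in {"ok", "regularized", "failed-defaulted"}.
cox_ladder <- function(x, time, event, control = NULL, fallback_l2 = 0.2) {
  if (length(x) != length(time) || length(time) != length(event)) {
    abort("feature, time and event lengths differ")
  }
  if (all(!event)) abort("all records censored: cannot fit a Cox model")

  df <- data.frame(time = time, event = event, x = x)
  has_control <- !is.null(control)
  if (has_control) df$ctrl <- control

  failed <- function(status) {
    list(log_hr = 0, ci_lo = NA_real_, ci_hi = NA_real_, p = 1, status = status)
  }
  # a degenerate feature carries no partial-likelihood information at all;
  # no rung of the ladder can identify it
  if (!all(is.finite(x)) || sd(x) == 0) return(failed("failed-defaulted"))
  extract <- function(fit, status) {
    beta <- unname(coef(fit))
    se <- sqrt(diag(fit$var))
    # the feature is always the first term in the formulas below
    b <- beta[1]
    s <- se[1]
    z <- b / s
    list(
      log_hr = b,
      ci_lo = b - 1.959963984540054 * s,
      ci_hi = b + 1.959963984540054 * s,
      p = 2 * pnorm(-abs(z)),
      status = status
    )
  }

  f0 <- if (has_control) Surv(time, event) ~ x + ctrl else Surv(time, event) ~ x
  r0 <- cox_try(f0, df)
  if (r0$ok) return(extract(r0$fit, "ok"))

  f1 <- if (has_control) {
    Surv(time, event) ~ ridge(x, ctrl, theta = fallback_l2, scale = FALSE)
  } else {
    Surv(time, event) ~ ridge(x, theta = fallback_l2, scale = FALSE)
  }
  r1 <- cox_try(f1, df)
  if (r1$ok) return(extract(r1$fit, "regularized"))
  failed("failed-defaulted")
}

# Multivariable fit with the same fallback ladder; returns NULL when both
# rungs fail. Used by the greedy multivariable pruning pass.
cox_multi_ladder <- function(X, time, event, fallback_l2 = 0.2) {
  X <- as.matrix(X)
  df <- data.frame(time = time, event = event)
  df$X <- X
  r0 <- cox_try(Surv(time, event) ~ X, df)
  if (r0$ok) {
    return(list(coef = unname(coef(r0$fit)), se = sqrt(diag(r0$fit$var)), status = "ok"))
  }
  r1 <- cox_try(Surv(time, event) ~ ridge(X, theta = fallback_l2, scale = FALSE), df)
  if (r1$ok) {
    return(list(coef = unname(coef(r1$fit)), se = sqrt(diag(r1$fit$var)), status = "regularized"))
  }
  NULL
}

# L2-penalized fit for final submodels and the fusion stage. Errors on
# nonconvergence: a final model must not silently default.
fit_cox_penalized <- function(X, time, event, l2) {
  X <- as.matrix(X)
  df <- data.frame(time = time, event = event)
  df$X <- X
  form <- if (l2 > 0) {
    Surv(time, event) ~ ridge(X, theta = l2, scale = FALSE)
  } else {
    Surv(time, event) ~ X
  }
  r <- cox_try(form, df)
  if (!r$ok) {
    abort(paste0(
      "penalized Cox fit failed to converge: ",
      paste(unique(r$notes), collapse = "; ")
    ))
  }
  list(
    coef = setNames(unname(coef(r$fit)), colnames(X)),
    se = setNames(sqrt(diag(r$fit$var)), colnames(X)),
    loglik = r$fit$loglik[length(r$fit$loglik)],
    n = r$fit$n,
    n_events = r$fit$nevent
  )
}
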
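# Evaluation battery: Harrell's concordance with bootstrap CI and
# permutation inference, Kaplan-Meier curves with threshold-searched risk
# groups and log-rank tests, survival-at-time interpolation, Kendall
# cross-modal concordance, and ordinal response association.
#
# Score orientation: risk scores follow the protective convention (negative
# log partial hazard, higher = longer expected survival), so for a
# comparable patient pair the one failing earlier should carry the LOWER
# score, and an informative model yields c > 0.5.

# Comparable pairs under right censoring: (i, j) with an observed event for
# i and time_i < time_j. Returns index vectors, used so that permutation
# and bootstrap loops are vectorized over pairs.
comparable_pairs <- function(time, event) {
  n <- length(time)
  cmp <- outer(time, time, "<") & matrix(event, n, n)
  idx <- which(cmp, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

c_from_pairs <- function(score, pairs) {
  si <- score[pairs$i]
  sj <- score[pairs$j]
  (sum(si < sj) + 0.5 * sum(si == sj)) / length(si)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs (earlier patient has an observed event), a
#' pair is concordant when the earlier-failing patient has the lower
#' (protective-oriented) score; score ties count 0.5.
#'
#' @param score Protective-oriented risk scores.
#' @param time,event Outcome vectors.
#' @return The c-index in `[0, 1]`.
#' @export
harrell_c <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  pairs <- comparable_pairs(time, event)
  if (length(pairs$i) == 0) abort("no comparable pairs")
  c_from_pairs(score, pairs)
}

#' Bootstrap confidence interval for the c-index
#'
#' Patients are resampled with replacement `n_reps` times; the CI is the
#' 2.5/97.5 percentile of the resampled c-indices. A resample with no
#' comparable pairs is redrawn (and counted in the `"redraws"` attribute).
#'
#' An alternative `"jackknife"` mode computes leave-one-out replicates and
#' a normal-theory interval from the jackknife variance.
#'
#' @param score,time,event As in [harrell_c()].
#' @param n_reps Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param method `"bootstrap"` (percentile, default) or `"jackknife"`.
#' @return Named numeric `c(lo, hi)` with attribute `"replicates"`.
#' @export
bootstrap_ci <- function(score, time, event, n_reps = 100, seed = 1L,
                         method = c("bootstrap", "jackknife")) {
  method <- match.arg(method)
  n <- length(score)
  if (method == "jackknife") {
    reps <- vapply(seq_len(n), function(i) {
      pairs <- comparable_pairs(time[-i], event[-i])
      if (length(pairs$i) == 0) return(NA_real_)
      c_from_pairs(score[-i], pairs)
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    m <- length(reps)
    se <- sqrt((m - 1) / m * sum((reps - mean(reps))^2))
    centre <- harrell_c(score, time, event)
    out <- setNames(pmin(pmax(centre + c(-1, 1) * 1.959963984540054 * se, 0), 1),
                    c("lo", "hi"))
    attr(out, "replicates") <- reps
    return(out)
  }
  reps <- numeric(n_reps)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        pairs <- comparable_pairs(time[idx], event[idx])
        if (length(pairs$i) > 0) break
        redraws <- redraws + 1L
      }
      reps[b] <- c_from_pairs(score[idx], pairs)
    }
  })
  out <- setNames(q_linear(reps, c(0.025, 0.975)), c("lo", "hi"))
  attr(out, "replicates") <- reps
  attr(out, "redraws") <- redraws
  out
}

#' One-sided permutation test for the c-index
#'
#' Scores are permuted against the fixed outcomes; the p-value is
#' `(1 + #{c_perm >= c_obs}) / (n_perm + 1)`, so it is never exactly zero
#' and significance claims stay conservative.
#'
#' @param score,time,event As in [harrell_c()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return The permutation p-value in `(0, 1]`.
#' @export
permutation_test <- function(score, time, event, n_perm = 1000, seed = 1L) {
  pairs <- comparable_pairs(time, event)
  if (length(pairs$i) == 0) abort("no comparable pairs")
  c_obs <- c_from_pairs(score, pairs)
  n <- length(score)
  hits <- 0L
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- score[sample.int(n)]
      if (c_from_pairs(perm, pairs) >= c_obs) hits <- hits + 1L
    }
  })
  (1 + hits) / (n_perm + 1)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate as a step function anchored at `S(0) = 1`.
#'
#' @param time,event Outcome vectors.
#' @return A `km_curve` tibble: `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1)
  fit <- survfit(Surv(time, event) ~ 1)
  out <- tibble(
    time = c(0, fit$time),
    surv = c(1, fit$surv),
    n_risk = c(length(time), fit$n.risk),
    n_event = c(0, fit$n.event)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Fraction surviving at a time point
#'
#' Linearly interpolates between adjacent points of the Kaplan-Meier step
#' function; beyond the last observed time the last estimate is carried
#' forward.
#'
#' @param curve A [km_curve()].
#' @param t Time (months), non-negative.
#' @return The interpolated fraction surviving.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) abort("`t` must be non-negative")
  approx(curve$time, curve$surv, xout = t, rule = 2, ties = "ordered")$y
}

#' Multivariate log-rank test
#'
#' Standard log-rank chi-square over k groups with k - 1 degrees of
#' freedom.
#'
#' @param time,event Outcome vectors.
#' @param group Group labels (at least two nonempty groups).
#' @return A list: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) abort("need at least two nonempty groups")
  if (sum(event) == 0) abort("no events in any group")
  fit <- survdiff(Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(statistic = fit$chisq, df = df, p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Search the risk-group percentile threshold on training data
#'
#' For each percentile in the grid, patients are split at that quantile of
#' the (protective-oriented) training scores -- scores at or below the cut
#' are the high-risk group -- and the training log-rank p-value of the
#' split is computed. The percentile minimizing the p-value wins; ties are
#' broken by proximity to 0.5, then by the lower percentile. Degenerate
#' splits (an empty group) are skipped. The chosen threshold is frozen as a
#' risk-score cut to be applied unchanged to test data; the search never
#' sees test outcomes.
#'
#' @param score Protective-oriented training risk scores.
#' @param time,event Training outcomes.
#' @param grid Percentile grid (default 0.33 to 0.66 by 0.01).
#' @param endpoint Label stored in the result.
#' @return A `risk_groups` object: list with `percentile`, `cut`,
#'   `train_p`, `groups` (tibble of the training assignment), `endpoint`.
#' @export
threshold_search <- function(score, time, event,
                             grid = seq(0.33, 0.66, by = 0.01),
                             endpoint = "OS") {
  stopifnot(length(grid) >= 1)
  best <- NULL
  for (q in grid) {
    cut <- q_linear(score, q)
    high <- score <= cut
    if (all(high) || !any(high)) next
    p <- tryCatch(logrank_test(time, event, ifelse(high, "high", "low"))$p,
                  error = function(e) NA_real_)
    # a degenerate variance (e.g. identical outcome multisets) carries no
    # evidence of separation
    if (is.na(p)) p <- 1
    cand <- list(percentile = q, cut = cut, train_p = p)
    if (is.null(best) ||
        p < best$train_p - 1e-12 ||
        (abs(p - best$train_p) <= 1e-12 &&
         (abs(q - 0.5) < abs(best$percentile - 0.5) - 1e-12 ||
          (abs(abs(q - 0.5) - abs(best$percentile - 0.5)) <= 1e-12 &&
           q < best$percentile)))) {
      best <- cand
    }
  }
  if (is.null(best)) abort("every threshold in the grid gave a degenerate split")
  best$groups <- tibble(
    score = score,
    group = ifelse(score <= best$cut, "high", "low")
  )
  best$endpoint <- endpoint
  class(best) <- "risk_groups"
  best
}

#' Apply a frozen risk-group threshold to new scores
#'
#' @param groups A `risk_groups` from [threshold_search()].
#' @param score New protective-oriented risk scores.
#' @return Character vector `"high"` / `"low"`.
#' @export
assign_risk_group <- function(groups, score) {
  stopifnot(inherits(groups, "risk_groups"))
  ifelse(score <= groups$cut, "high", "low")
}

#' @export
print.risk_groups <- function(x, ...) {
  cat(sprintf("<risk_groups> %s: percentile %.2f (score cut %.4g), training log-rank p = %.3g\n",
              x$endpoint, x$percentile, x$cut, x$train_p))
  print(table(x$groups$group))
  invisible(x)
}

#' Kendall rank correlation between two modalities' risk orderings
#'
#' Each modality's scores are converted to risk quantiles within its own
#' available set; tau-b is then computed over the patients with both
#' modalities present.
#'
#' @param scores Score table (`id` plus modality columns).
#' @param pair Character vector of two modality names.
#' @return Kendall's tau-b.
#' @export
kendall_cross_modal <- function(scores, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(scores)))
  x <- scores[[pair[1]]]
  y <- scores[[pair[2]]]
  qx <- rank(x, na.last = "keep") / sum(!is.na(x))
  qy <- rank(y, na.last = "keep") / sum(!is.na(y))
  ok <- !is.na(qx) & !is.na(qy)
  if (sum(ok) < 2) abort("fewer than 2 complete pairs")
  cor(qx[ok], qy[ok], method = "kendall")
}

#' Pairwise Kendall matrix over all modalities in a score table
#'
#' @param scores Score table (`id` plus modality columns).
#' @return A tibble (`modality_a`, `modality_b`, `tau`, `n`).
#' @export
kendall_matrix <- function(scores) {
  mods <- feature_cols(scores)
  rows <- list()
  for (a in seq_along(mods)) {
    for (b in seq_along(mods)) {
      if (b <= a) next
      ok <- !is.na(scores[[mods[a]]]) & !is.na(scores[[mods[b]]])
      tau <- if (sum(ok) >= 2) kendall_cross_modal(scores, c(mods[a], mods[b])) else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        modality_a = mods[a], modality_b = mods[b], tau = tau, n = sum(ok)
      )
    }
  }
  bind_rows(rows)
}

#' One-sided Mann-Whitney association between scores and an ordinal label
#'
#' Tests whether scores in stratum `x` tend to exceed those in stratum `y`
#' (`alternative = "greater"`) or fall below them (`"less"`). For combined
#' n of at most 20 the p-value is computed by exact enumeration of all
#' label assignments (ties handled through midranks); larger samples use
#' the normal approximation with tie correction.
#'
#' @param x,y Score vectors for the two strata (both nonempty).
#' @param alternative `"greater"` or `"less"`.
#' @return The one-sided p-value.
#' @export
mann_whitney_ordinal <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("both strata must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n <= 20) {
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sets <- combn(n, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    if (alternative == "greater") {
      mean(u_all >= u_obs - eps)
    } else {
      mean(u_all <= u_obs + eps)
    }
  } else {
    wilcox.test(x, y, alternative = alternative, exact = FALSE,
                correct = TRUE)$p.value
  }
}

#' Association between fused risk scores and chemotherapy response
#'
#' One-sided Mann-Whitney U-test comparing the (protective-oriented) scores
#' of good responders against the rest: under the expected direction, good
#' responders carry higher protective scores.
#'
#' @param score Protective-oriented scores.
#' @param crs Ordinal response labels (higher = better response); `NA`
#'   labels are dropped.
#' @param good_level Levels counted as good response (default: the
#'   maximum observed level).
#' @param alternative Direction of the test, as in
#'   [mann_whitney_ordinal()].
#' @return A list: `p`, `n_good`, `n_other`.
#' @export
crs_association <- function(score, crs, good_level = NULL,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- !is.na(crs) & !is.na(score)
  score <- score[ok]; crs <- crs[ok]
  if (is.null(good_level)) good_level <- max(crs)
  good <- crs %in% good_level
  if (!any(good) || all(good)) abort("a CRS stratum is empty")
  list(
    p = mann_whitney_ordinal(score[good], score[!good], alternative),
    n_good = sum(good), n_other = sum(!good)
  )
}

#' Evaluate a set of risk scores against outcomes
#'
#' Bundles the c-index, its bootstrap CI, the permutation p-value and the
#' sample accounting into one report row.
#'
#' @param scores Tibble (`id`, `score`), protective-oriented; missing
#'   scores are dropped.
#' @param outcomes Outcomes tibble (`id`, `time`, `event`).
#' @param n_boot Bootstrap resamples for the CI.
#' @param n_perm Permutations for the p-value.
#' @param seed Integer seed (expanded into independent substreams).
#' @return An `mm_eval` one-row tibble: `c_index`, `ci_lo`, `ci_hi`,
#'   `perm_p`, `n`, `n_events`.
#' @export
evaluate_risks <- function(scores, outcomes, n_boot = 100, n_perm = 1000,
                           seed = 1L) {
  check_outcomes(outcomes)
  joined <- inner_join(scores, outcomes, by = "id")
  joined <- joined[!is.na(joined$score), , drop = FALSE]
  if (nrow(joined) < 2) abort("fewer than 2 scored patients")
  ci <- bootstrap_ci(joined$score, joined$time, joined$event,
                     n_reps = n_boot, seed = substream_seed(seed, "bootstrap"))
  out <- tibble(
    c_index = harrell_c(joined$score, joined$time, joined$event),
    ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
    perm_p = permutation_test(joined$score, joined$time, joined$event,
                              n_perm = n_perm,
                              seed = substream_seed(seed, "permutation")),
    n = nrow(joined), n_events = sum(joined$event)
  )
  class(out) <- c("mm_eval", class(out))
  out
}
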
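# Independent oracles used by the tests. Each is a direct transcription of
# the defining formula, deliberately naive (loops, enumeration, generic
# optimizers) and sharing no code with the package internals it checks.

# Efron log partial likelihood, written from the formula: for each distinct
# event time with event set D (size d) and risk set R,
#   sum_{i in D} eta_i - sum_{k=0}^{d-1} log( S_R - (k/d) * S_D )
# with S_R = sum over risk set of exp(eta), S_D = sum over D of exp(eta).
oracle_efron_loglik <- function(beta, X, time, event) {
  eta <- as.vector(as.matrix(X) %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    D <- which(event & time == t)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (k in seq_len(d) - 1) {
      ll <- ll - log(sum(w[R]) - (k / d) * sum(w[D]))
    }
  }
  ll
}

# Numeric maximizer of the (optionally L2-penalized) Efron objective.
oracle_cox_optimum <- function(X, time, event, l2 = 0) {
  X <- as.matrix(X)
  obj <- function(b) {
    -(oracle_efron_loglik(b, X, time, event) - (l2 / 2) * sum(b^2))
  }
  if (ncol(X) == 1) {
    stats::optimize(function(b) obj(b), interval = c(-20, 20), tol = 1e-10)$minimum
  } else {
    fit <- stats::optim(rep(0, ncol(X)), obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 2000))
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
    fit2$par
  }
}

# Harrell's c by exhaustive pair enumeration (double loop).
oracle_harrell_c <- function(score, time, event) {
  num <- 0
  den <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] && time[i] < time[j]) {
        den <- den + 1
        if (score[i] < score[j]) num <- num + 1
        if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Benjamini-Hochberg step-up by its closed form.
oracle_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below) > 0) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Two-group log-rank statistic from per-event-time hypergeometric moments.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(length(unique(g)) == 2)
  obs_minus_exp <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g == 1)
    obs_minus_exp <- obs_minus_exp + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  obs_minus_exp^2 / v
}

# Kendall tau-b by pair enumeration.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  nc <- 0; nd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1
      if (s < 0) nd <- nd + 1
    }
  }
  n0 <- choose(n, 2)
  t1 <- sum(choose(table(x), 2))
  t2 <- sum(choose(table(y), 2))
  (nc - nd) / sqrt((n0 - t1) * (n0 - t2))
}

# Ellipse-of-equal-second-moments shape descriptors of a mask, computed by
# an explicit pixel loop.
oracle_mask_moments <- function(mask, ps = 1) {
  nr <- nrow(mask)
  xs <- c(); ys <- c()
  for (r in seq_len(nr)) {
    for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc]) {
        xs <- c(xs, cc - 1)
        ys <- c(ys, r - 1)
      }
    }
  }
  n <- length(xs)
  mx <- sum(xs) / n; my <- sum(ys) / n
  mu20 <- sum((xs - mx)^2) / n
  mu02 <- sum((ys - my)^2) / n
  mu11 <- sum((xs - mx) * (ys - my)) / n
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2))$values
  list(
    area = n * ps^2,
    major = 4 * sqrt(max(ev)) * ps,
    minor = 4 * sqrt(max(min(ev), 0)) * ps,
    eccentricity = if (max(ev) > 0) sqrt(1 - min(ev) / max(ev)) else 0
  )
}

# Random censored survival instance for oracle-equivalence loops.
random_surv_instance <- function(n, p = 0, censor = 0.3) {
  X <- if (p > 0) matrix(rnorm(n * p), n, p) else NULL
  eta <- if (p > 0) as.vector(X %*% rnorm(p, 0, 0.5)) else rep(0, n)
  t_event <- rexp(n, exp(eta))
  t_cens <- if (censor > 0) rexp(n, censor * exp(mean(eta))) else rep(Inf, n)
  list(
    X = X,
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    score = rnorm(n)
  )
}
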
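#' Simulate a multimodal survival cohort with known ground truth
#'
#' Draws per-patient feature blocks, clinical covariates, an HRD label and
#' right-censored OS/PFS outcomes under a proportional-hazards model whose
#' true linear predictor is the sum of the planted feature effects, the HRD
#' effect and the planted clinical effects. Event times come from a Weibull
#' baseline hazard scaled by `exp(linear predictor)`; censoring times are
#' independent exponentials whose rate is solved numerically so the expected
#' censored fraction matches `censoring_rate_target`. Per-modality
#' availability is drawn independently per patient; unavailable patients
#' still carry their (unobserved) biology in the true linear predictor.
#'
#' @param config A [sim_config()] object.
#' @return An `mm_cohort`: list with `manifest` (one row per patient),
#'   `features` (named list of id + feature tibbles, available patients
#'   only), `truth` (id and true linear predictor) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' cohort$manifest
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  # shared factor for cross-modality correlation of planted features
  shared <- rnorm(n)

  blocks <- list()
  lp <- numeric(n)
  for (m in names(config$n_features)) {
    p <- config$n_features[[m]]
    planted_idx <- config$planted$index[config$planted$modality == m]
    X <- simulate_feature_block(
      n, p,
      planted_idx = planted_idx,
      rho = config$decoy_block_correlation,
      block_size = config$decoy_block_size,
      near_constant_fraction = config$near_constant_fraction,
      shared = shared,
      cross_r = config$cross_modality_correlation
    )
    colnames(X) <- sprintf("%s_%04d", m, seq_len(p))
    blocks[[m]] <- X
    betas <- config$planted$log_hr[config$planted$modality == m]
    if (length(planted_idx) > 0) {
      lp <- lp + as.vector(X[, planted_idx, drop = FALSE] %*% betas)
    }
  }

  # genomic ground truth and observed call
  hrd_true <- runif(n) < config$hrd_prevalence
  hrd_known <- runif(n) < config$hrd_known_prob
  hrd_call <- ifelse(hrd_known, ifelse(hrd_true, "HRD", "HRP"), "ambiguous")
  lp <- lp + config$hrd_log_hr * hrd_true

  # clinical covariates; frequencies approximate a late-stage surgical cohort
  rd_status <- sample(c("<=1cm", ">1cm", "unknown"), n, replace = TRUE,
                      prob = c(0.60, 0.35, 0.05))
  parpi <- runif(n) < 0.15
  age <- round(pmin(pmax(rnorm(n, 63, 9), 30), 92), 1)
  stage <- sample(c("I", "II", "III", "IV", "unknown"), n, replace = TRUE,
                  prob = c(8, 10, 225, 160, 1) / 404)
  treatment <- sample(c("NACT-IDS", "PDS", "unknown"), n, replace = TRUE,
                      prob = c(175, 82, 147) / 404)
  adnexal_present <- runif(n) < 245 / 404
  lp <- lp + config$clinical_log_hr[["rd"]] * (rd_status == "<=1cm") +
    config$clinical_log_hr[["parpi"]] * parpi

  os <- draw_survival(lp, config$baseline$shape, config$baseline$scale,
                      config$censoring_rate_target)
  pfs <- draw_survival(lp, config$baseline$shape, config$pfs_scale,
                       config$censoring_rate_target)

  # ordinal CRS: higher = better pathological response, shifted by -risk
  latent <- -lp + rlogis(n)
  crs_val <- 1L + findInterval(latent, sort(config$crs_cutpoints))
  crs <- ifelse(runif(n) < config$crs_known_prob, crs_val, NA_integer_)

  avail <- map(config$availability, ~ runif(n) < .x)

  manifest <- tibble(
    id = ids,
    os_months = os$time, os_event = os$event,
    pfs_months = pfs$time, pfs_event = pfs$event,
    stage = stage, rd_status = rd_status, treatment = treatment,
    parpi = parpi, age = age, adnexal_present = adnexal_present,
    hrd_call = hrd_call, crs = crs
  )
  for (m in names(avail)) manifest[[paste0("has_", m)]] <- avail[[m]]

  features <- imap(blocks, function(X, m) {
    keep <- avail[[m]]
    bind_cols(tibble(id = ids[keep]), as_tibble(X[keep, , drop = FALSE]))
  })

  structure(
    list(
      manifest = manifest,
      features = features,
      truth = tibble(id = ids, lp = lp),
      config = config
    ),
    class = "mm_cohort"
  )
}

# One modality's feature block: planted columns (optionally sharing a
# cross-modality factor), equicorrelated Gaussian decoy blocks, and a
# trailing near-constant slice whose scaled IQR is < 0.1 by construction
# (a tight Gaussian core plus two unit-magnitude sentinels that pin the
# min-max range).
simulate_feature_block <- function(n, p, planted_idx, rho, block_size,
                                   near_constant_fraction, shared, cross_r) {
  X <- matrix(NA_real_, n, p)
  n_nc <- floor(near_constant_fraction * p)
  nc_idx <- setdiff(seq(p, 1L), planted_idx)[seq_len(min(n_nc, p - length(planted_idx)))]
  decoy_idx <- setdiff(seq_len(p), c(planted_idx, nc_idx))

  for (j in planted_idx) {
    X[, j] <- if (cross_r > 0) {
      sqrt(cross_r) * shared + sqrt(1 - cross_r) * rnorm(n)
    } else {
      rnorm(n)
    }
  }

  if (length(decoy_idx) > 0) {
    n_blocks <- ceiling(length(decoy_idx) / block_size)
    assignment <- rep(seq_len(n_blocks), each = block_size)[seq_along(decoy_idx)]
    factors <- matrix(rnorm(n * n_blocks), n, n_blocks)
    noise <- matrix(rnorm(n * length(decoy_idx)), n, length(decoy_idx))
    X[, decoy_idx] <- sqrt(rho) * factors[, assignment, drop = FALSE] +
      sqrt(1 - rho) * noise
  }

  if (length(nc_idx) > 0) {
    # a sparse unit-magnitude spike (10% of patients) plus tiny jitter: the
    # spikes pin the min-max range far outside the quartiles, so the scaled
    # IQR stays well below 0.1 under any realistic patient subset
    for (j in nc_idx) {
      X[, j] <- (runif(n) < 0.1) + rnorm(n, 0, 0.005)
    }
  }
  X
}

# Event/censoring times under a Weibull baseline scaled by exp(lp).
# S(t | lp) = exp(-(t/scale)^shape * exp(lp)); inversion gives the draw.
# The exponential censoring rate is solved so that, conditional on the
# drawn event times, the expected censored fraction equals the target.
draw_survival <- function(lp, shape, scale, censor_target) {
  n <- length(lp)
  u <- runif(n)
  t_event <- scale * (-log(u) * exp(-lp))^(1 / shape)
  if (censor_target <= 0) {
    return(list(time = t_event, event = rep(TRUE, n)))
  }
  expected_censored <- function(rate) mean(1 - exp(-rate * t_event))
  hi <- 1
  while (expected_censored(hi) < censor_target && hi < 1e6) hi <- hi * 2
  rate <- uniroot(function(r) expected_censored(r) - censor_target,
                  lower = 1e-10, upper = hi, tol = 1e-12)$root
  t_cens <- rexp(n, rate)
  list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat("<mm_cohort> ", nrow(x$manifest), " patients\n", sep = "")
  for (m in names(x$features)) {
    cat(sprintf("  %s: %d features, %d patients available\n",
                m, length(feature_cols(x$features[[m]])), nrow(x$features[[m]])))
  }
  cat("  censored OS fraction:", round(mean(!x$manifest$os_event), 3), "\n")
  invisible(x)
}
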
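# Shared helpers. Quantiles everywhere in the package use the linear
# interpolation convention (stats::quantile type = 7); this is relied on by
# the scaled-IQR filter, percentile features and risk-group thresholds.

q_linear <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' A single user-facing seed is expanded into per-stage seeds so that a
#' change in one stage's configuration does not perturb the random draws of
#' the others. The mapping is a fixed affine hash kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, split = 2L, bootstrap = 3L, permutation = 4L,
    tissue = 5L, selection = 6L, evaluation = 7L, misc = 8L
  )
  off <- offsets[[match.arg(stage, names(offsets))]]
  as.integer((as.numeric(seed) * 131071 + off * 524287) %% 2147483629)
}

# Run code with a local RNG state (seed-scoped, restores .Random.seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate an outcomes data frame (id, time, event).
check_outcomes <- function(outcomes, arg = "outcomes") {
  stopifnot(is.data.frame(outcomes))
  need <- c("id", "time", "event")
  miss <- setdiff(need, names(outcomes))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(outcomes$time)) || any(outcomes$time <= 0)) {
    abort(sprintf("`%s$time` must be finite and positive", arg))
  }
  if (!is.logical(outcomes$event)) {
    abort(sprintf("`%s$event` must be logical", arg))
  }
  invisible(outcomes)
}

# Extract endpoint-specific outcomes from a cohort manifest.
manifest_outcomes <- function(manifest, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") {
    tibble(id = manifest$id, time = manifest$os_months, event = manifest$os_event)
  } else {
    tibble(id = manifest$id, time = manifest$pfs_months, event = manifest$pfs_event)
  }
}

feature_cols <- function(data) setdiff(names(data), "id")

modality_levels <- c("genomic", "radiomic", "histopathology", "clinical")

combo_label <- function(modalities) {
  initials <- c(genomic = "G", radiomic = "R", histopathology = "H", clinical = "C")
  paste(initials[match(modalities, names(initials))], collapse = "")
}
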
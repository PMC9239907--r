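# End-to-end replication driver: train/test split, per-modality selection
# and fitting, fusion combinations, and a consolidated comparison report.

#' Configuration for the end-to-end pipeline
#'
#' @param endpoint `"OS"` or `"PFS"`.
#' @param modalities Modalities to build (subset of genomic, radiomic,
#'   histopathology, clinical).
#' @param combos List of modality combinations to fuse and evaluate; every
#'   combination must be a subset of `modalities`.
#' @param selection Named list of [selection_config()]s per feature
#'   modality. Radiomics defaults to Benjamini-Hochberg correction (the
#'   largest feature space); histopathology controls for relative specimen
#'   size when that feature is present.
#' @param clinical_mode `"select"` runs the generic cascade on the encoded
#'   clinical matrix; `"fixed"` uses the published two-feature clinical
#'   signature (RD status and PARP-inhibitor receipt).
#' @param n_test Held-out test-set size, sampled from the full-information
#'   patients.
#' @param n_boot,n_perm Evaluation replication counts.
#' @param threshold_grid Percentile grid for the risk-group search.
#' @param l2 L2 strength for all final (unimodal and fusion) models.
#' @param restrict_full_information Train every stage only on
#'   full-information patients (the ablation arm) instead of all available
#'   unimodal cases.
#' @param seed Master seed; stages draw from named substreams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(endpoint = c("OS", "PFS"),
                            modalities = c("genomic", "radiomic",
                                           "histopathology", "clinical"),
                            combos = default_combos(modalities),
                            selection = default_selection(modalities),
                            clinical_mode = c("select", "fixed"),
                            n_test = 40L,
                            n_boot = 100L,
                            n_perm = 1000L,
                            threshold_grid = seq(0.33, 0.66, by = 0.01),
                            l2 = 0.5,
                            restrict_full_information = FALSE,
                            seed = 1L) {
  endpoint <- match.arg(endpoint)
  clinical_mode <- match.arg(clinical_mode)
  modalities <- match.arg(modalities, modality_levels, several.ok = TRUE)
  for (cmb in combos) {
    if (!all(cmb %in% modalities)) {
      abort(sprintf("combination {%s} references modalities outside the configured list",
                    paste(cmb, collapse = ", ")))
    }
  }
  structure(
    list(endpoint = endpoint, modalities = modalities, combos = combos,
         selection = selection, clinical_mode = clinical_mode,
         n_test = as.integer(n_test), n_boot = as.integer(n_boot),
         n_perm = as.integer(n_perm), threshold_grid = threshold_grid,
         l2 = l2, restrict_full_information = restrict_full_information,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @export
default_combos <- function(modalities = modality_levels) {
  singles <- as.list(modalities)
  extra <- list(
    c("radiomic", "histopathology"),
    c("genomic", "radiomic", "histopathology"),
    c("genomic", "radiomic", "histopathology", "clinical")
  )
  keep(c(singles, extra), ~ all(.x %in% modalities))
}

#' @rdname pipeline_config
#' @export
default_selection <- function(modalities = modality_levels) {
  sel <- list(
    radiomic = selection_config(apply_bh = TRUE),
    histopathology = selection_config(),
    clinical = selection_config()
  )
  sel[intersect(names(sel), modalities)]
}

#' Sample the held-out test split from full-information patients
#'
#' Test cases are drawn uniformly without replacement from patients with
#' every feature modality available, an unambiguous HRD call and a known
#' stage, so every model can be compared on the same patients.
#'
#' @param cohort An `mm_cohort`.
#' @param n_test Number of test patients (0 gives a train-only split with a
#'   warning).
#' @param seed Integer seed.
#' @return A tibble (`id`, `split`) with split in `{"train", "test"}`.
#' @export
make_test_split <- function(cohort, n_test = 40L, seed = 1L) {
  manifest <- cohort$manifest
  eligible <- rep(TRUE, nrow(manifest))
  for (m in names(cohort$features)) {
    eligible <- eligible & manifest[[paste0("has_", m)]]
  }
  if ("hrd_call" %in% names(manifest)) {
    eligible <- eligible & manifest$hrd_call != "ambiguous"
  }
  if ("stage" %in% names(manifest)) {
    eligible <- eligible & manifest$stage != "unknown"
  }
  if (n_test == 0) {
    warn("empty test set requested; the pipeline will run train-only")
    return(tibble(id = manifest$id, split = "train"))
  }
  if (sum(eligible) < n_test) {
    abort(sprintf("only %d full-information patients; cannot sample %d test cases",
                  sum(eligible), n_test))
  }
  test_ids <- with_seed(seed, sample(manifest$id[eligible], n_test))
  tibble(id = manifest$id,
         split = ifelse(manifest$id %in% test_ids, "test", "train"))
}

full_information_ids <- function(cohort) {
  manifest <- cohort$manifest
  ok <- rep(TRUE, nrow(manifest))
  for (m in names(cohort$features)) ok <- ok & manifest[[paste0("has_", m)]]
  if ("hrd_call" %in% names(manifest)) ok <- ok & manifest$hrd_call != "ambiguous"
  manifest$id[ok]
}

#' Run the full late-fusion pipeline on a cohort
#'
#' Executes, per feature modality: the selection cascade on the training
#' cases with that modality available, the final L2-penalized submodel, and
#' risk prediction for every available patient. Assembles the per-modality
#' score table (genomic risk from the HRD calls), then for each configured
#' combination fits the second-stage fusion model on the training
#' intersection set, evaluates train and test concordance (bootstrap CI,
#' permutation p), searches the risk-group threshold on training data and
#' applies the frozen cut to the test set. Cross-modal Kendall concordance
#' and the CRS association are computed on training patients. No stage ever
#' fits on test outcomes.
#'
#' @param cohort An `mm_cohort`.
#' @param config A [pipeline_config()].
#' @param split Optional precomputed split tibble (`id`, `split`);
#'   defaults to [make_test_split()] under the config's split substream.
#' @return An `mm_report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), split = NULL) {
  stopifnot(inherits(cohort, "mm_cohort"), inherits(config, "pipeline_config"))
  feature_mods <- intersect(config$modalities, names(cohort$features))
  missing_mods <- setdiff(config$modalities,
                          c("genomic", "clinical", names(cohort$features)))
  if (length(missing_mods) > 0) {
    abort(paste0("cohort lacks feature modalities: ",
                 paste(missing_mods, collapse = ", ")))
  }

  if (is.null(split)) {
    split <- make_test_split(cohort, config$n_test,
                             seed = substream_seed(config$seed, "split"))
  }
  train_ids <- split$id[split$split == "train"]
  if (config$restrict_full_information) {
    train_ids <- intersect(train_ids, full_information_ids(cohort))
  }
  test_ids <- split$id[split$split == "test"]
  outcomes <- manifest_outcomes(cohort$manifest, config$endpoint)
  train_out <- outcomes[outcomes$id %in% train_ids, , drop = FALSE]

  log_rows <- list()
  note <- function(stage, detail, n) {
    log_rows[[length(log_rows) + 1]] <<- tibble(stage = stage, detail = detail, n = n)
  }

  train_manifest <- cohort$manifest[cohort$manifest$id %in% train_ids, , drop = FALSE]
  clinical_all <- NULL
  signatures <- list()
  submodels <- list()

  for (m in setdiff(config$modalities, "genomic")) {
    if (m == "clinical") {
      clinical_train <- encode_clinical(train_manifest)
      clinical_all <- encode_clinical(cohort$manifest,
                                      age_range = attr(clinical_train, "age_range"))
      data_train <- clinical_train
    } else {
      fm <- cohort$features[[m]]
      data_train <- fm[fm$id %in% train_ids, , drop = FALSE]
    }
    note(m, "training cases available", nrow(data_train))

    if (m == "clinical" && config$clinical_mode == "fixed") {
      signature <- tibble(feature = c("rd", "parpi"),
                          log_hr = NA_real_, p = NA_real_)
      class(signature) <- c("mm_signature", class(signature))
    } else {
      sel_cfg <- config$selection[[m]] %||% selection_config()
      signature <- select_modality(data_train, train_out, sel_cfg)
    }
    signatures[[m]] <- signature
    note(m, "signature size", nrow(signature))
    if (nrow(signature) == 0) {
      inform(sprintf("modality '%s': empty signature; submodel skipped", m))
      next
    }
    submodels[[m]] <- fit_submodel(data_train, train_out, signature,
                                   l2 = config$l2, modality = m)
  }

  scores <- assemble_submodel_scores(cohort, submodels, clinical = clinical_all)
  scores <- scores[, c("id", intersect(config$modalities, names(scores))),
                   drop = FALSE]
  train_scores <- scores[scores$id %in% train_ids, , drop = FALSE]
  test_scores <- scores[scores$id %in% test_ids, , drop = FALSE]

  combo_rows <- list()
  fusion_models <- list()
  risk_groups <- list()
  for (cmb in config$combos) {
    label <- combo_label(cmb)
    usable <- intersect(cmb, names(scores))
    if (length(usable) < length(cmb)) {
      inform(sprintf("combination %s skipped: no submodel for %s", label,
                     paste(setdiff(cmb, usable), collapse = ", ")))
      next
    }
    fus <- fit_fusion(train_scores, train_out, cmb, l2 = config$l2)
    fusion_models[[label]] <- fus
    fused_all <- predict_fused(fus, scores)
    fused_train <- fused_all[fused_all$id %in% train_ids, , drop = FALSE]
    fused_test <- fused_all[fused_all$id %in% test_ids, , drop = FALSE]

    ev_train <- evaluate_risks(fused_train, outcomes,
                               n_boot = config$n_boot, n_perm = config$n_perm,
                               seed = substream_seed(config$seed, "evaluation"))
    ok_train <- inner_join(fused_train, train_out, by = "id")
    ok_train <- ok_train[!is.na(ok_train$score), , drop = FALSE]
    rg <- threshold_search(ok_train$score, ok_train$time, ok_train$event,
                           grid = config$threshold_grid,
                           endpoint = config$endpoint)
    risk_groups[[label]] <- rg

    if (nrow(fused_test) > 0) {
      ev_test <- evaluate_risks(fused_test, outcomes,
                                n_boot = config$n_boot, n_perm = config$n_perm,
                                seed = substream_seed(config$seed, "evaluation"))
      test_joined <- inner_join(fused_test, outcomes, by = "id")
      test_joined <- test_joined[!is.na(test_joined$score), , drop = FALSE]
      grp <- assign_risk_group(rg, test_joined$score)
      lr_test <- if (length(unique(grp)) == 2 && sum(test_joined$event) > 0) {
        logrank_test(test_joined$time, test_joined$event, grp)$p
      } else {
        NA_real_
      }
    } else {
      ev_test <- tibble(c_index = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        perm_p = NA_real_, n = 0L, n_events = 0L)
      lr_test <- NA_real_
    }

    combo_rows[[label]] <- tibble(
      combo = label,
      n_train = fus$n_intersection,
      train_c = ev_train$c_index,
      train_perm_p = ev_train$perm_p,
      threshold = rg$percentile,
      train_logrank_p = rg$train_p,
      n_test = ev_test$n,
      test_c = ev_test$c_index,
      test_ci_lo = ev_test$ci_lo,
      test_ci_hi = ev_test$ci_hi,
      test_perm_p = ev_test$perm_p,
      test_logrank_p = lr_test
    )
  }

  kendall <- kendall_matrix(train_scores)
  crs_rows <- list()
  crs_train <- cohort$manifest[cohort$manifest$id %in% train_ids,
                               c("id", "crs"), drop = FALSE]
  for (label in names(fusion_models)) {
    fused <- predict_fused(fusion_models[[label]], scores)
    j <- inner_join(fused, crs_train, by = "id")
    j <- j[!is.na(j$crs) & !is.na(j$score), , drop = FALSE]
    p <- if (nrow(j) >= 4 && length(unique(j$crs == max(j$crs))) == 2) {
      tryCatch(crs_association(j$score, j$crs)$p, error = function(e) NA_real_)
    } else {
      NA_real_
    }
    crs_rows[[label]] <- tibble(combo = label, crs_p = p, n = nrow(j))
  }

  structure(
    list(
      config = config, split = split,
      signatures = signatures, submodels = submodels,
      fusion_models = fusion_models,
      scores = scores,
      comparison = bind_rows(combo_rows),
      risk_groups = risk_groups,
      kendall = kendall,
      crs = bind_rows(crs_rows),
      log = bind_rows(log_rows)
    ),
    class = "mm_report"
  )
}

#' @export
print.mm_report <- function(x, ...) {
  cat("<mm_report> endpoint:", x$config$endpoint, "\n")
  cat("combinations evaluated:\n")
  print(x$comparison)
  invisible(x)
}

#' Compare training on all available cases against full-information cases
#'
#' Runs the pipeline twice on the same cohort and split: once with every
#' submodel trained on all of its available unimodal training cases, and
#' once with the entire cascade restricted to patients with complete
#' information. Reports the test concordance of both arms per combination.
#'
#' @param cohort An `mm_cohort` (with missingness).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per arm and combination.
#' @export
ablation_full_information <- function(cohort, config = pipeline_config()) {
  split <- make_test_split(cohort, config$n_test,
                           seed = substream_seed(config$seed, "split"))
  cfg_b <- config
  cfg_b$restrict_full_information <- TRUE
  # the restricted arm drops the radiomic multiple-testing correction: with
  # full-information cases only, no radiomic feature survives it
  if (!is.null(cfg_b$selection$radiomic)) {
    cfg_b$selection$radiomic$apply_bh <- FALSE
  }
  arms <- list(all_available = config, full_information_only = cfg_b)
  bind_rows(imap(arms, function(cfg, arm) {
    rep <- tryCatch(run_pipeline(cohort, cfg, split = split),
                    error = function(e) NULL)
    if (is.null(rep) || nrow(rep$comparison) == 0) {
      warn(sprintf("arm '%s' produced no evaluable combination", arm))
      return(tibble(arm = arm, combo = character(), n_train = integer(),
                    test_c = numeric()))
    }
    tibble(arm = arm, combo = rep$comparison$combo,
           n_train = rep$comparison$n_train,
           test_c = rep$comparison$test_c)
  }))
}

#' Write a report bundle to a directory
#'
#' Deterministic JSON + TSV serialization of the comparison table, the
#' per-patient score table, the signatures, the Kendall matrix, the CRS
#' associations and the stage log: rerunning the pipeline with the same
#' configuration reproduces the bundle byte for byte.
#'
#' @param report An `mm_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "mm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$comparison, file.path(dir, "comparison.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$scores, file.path(dir, "scores.tsv"), progress = FALSE)
  readr::write_tsv(report$kendall, file.path(dir, "kendall.tsv"), progress = FALSE)
  readr::write_tsv(report$crs, file.path(dir, "crs.tsv"), progress = FALSE)
  readr::write_tsv(report$log, file.path(dir, "stage_log.tsv"), progress = FALSE)
  readr::write_tsv(report$split, file.path(dir, "split.tsv"), progress = FALSE)
  sig <- bind_rows(imap(report$signatures, function(s, m) {
    if (nrow(s) == 0) return(tibble(modality = character(), feature = character(),
                                    log_hr = numeric(), p = numeric()))
    tibble(modality = m, feature = s$feature, log_hr = s$log_hr, p = s$p)
  }))
  readr::write_tsv(sig, file.path(dir, "signatures.tsv"), progress = FALSE)
  summary <- list(
    endpoint = report$config$endpoint,
    seed = report$config$seed,
    combos = map_chr(report$config$combos, combo_label),
    submodels = map(report$submodels, function(m) {
      list(modality = m$modality, features = m$features,
           coef = as.list(m$coef), l2 = m$l2, n = m$n, n_events = m$n_events)
    }),
    fusion = map(report$fusion_models, function(f) {
      list(modalities = f$modalities, coef = as.list(f$coef),
           n_intersection = f$n_intersection)
    })
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(dir)
}
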
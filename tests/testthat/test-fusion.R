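# Cohorts with two independent planted modality signals, full availability
# unless stated, used to probe the fusion stage.
fusion_cohort <- function(seed, n = 600, beta = c(0.4, 0.4),
                          availability = c(radiomic = 1, histopathology = 1),
                          censor = 0.15, cross_r = 0) {
  simulate_cohort(sim_config(
    n_patients = n,
    n_features = c(radiomic = 4L, histopathology = 4L),
    planted = tibble::tibble(
      modality = c("radiomic", "histopathology"),
      index = c(1L, 1L), log_hr = beta
    ),
    availability = availability,
    censoring_rate_target = censor,
    cross_modality_correlation = cross_r,
    hrd_log_hr = -0.45,
    clinical_log_hr = c(rd = 0, parpi = 0),
    seed = seed
  ))
}

fit_both_submodels <- function(cohort, out) {
  list(
    radiomic = fit_submodel(
      cohort$features$radiomic[cohort$features$radiomic$id %in% out$id, ],
      out, "radiomic_0001", modality = "radiomic"),
    histopathology = fit_submodel(
      cohort$features$histopathology[cohort$features$histopathology$id %in% out$id, ],
      out, "histopathology_0001", modality = "histopathology")
  )
}

test_that("the score table preserves missingness patterns", {
  ch <- fusion_cohort(1, n = 300,
                      availability = c(radiomic = 0.6, histopathology = 0.6))
  out <- mmfuse:::manifest_outcomes(ch$manifest, "OS")
  sub <- fit_both_submodels(ch, out)
  scores <- assemble_submodel_scores(ch, sub)
  m <- ch$manifest

  no_ct <- m$id[!m$has_radiomic][1]
  expect_true(is.na(scores$radiomic[scores$id == no_ct]))
  amb <- m$id[m$hrd_call == "ambiguous"][1]
  expect_true(is.na(scores$genomic[scores$id == amb]))

  full <- m$id[m$has_radiomic & m$has_histopathology & m$hrd_call != "ambiguous"][1]
  row <- scores[scores$id == full, ]
  expect_false(anyNA(row))
})

test_that("fusing a single modality preserves the submodel ordering", {
  ch <- fusion_cohort(2, n = 300)
  out <- mmfuse:::manifest_outcomes(ch$manifest, "OS")
  sub <- fit_both_submodels(ch, out)
  scores <- assemble_submodel_scores(ch, sub)
  fus <- fit_fusion(scores, out, "radiomic")
  fused <- predict_fused(fus, scores)
  # monotone transform of the unimodal (risk-oriented) score
  expect_equal(order(fused$score), order(-scores$radiomic))
})

test_that("duplicated score columns add no ordering information", {
  ch <- fusion_cohort(3, n = 400)
  out <- mmfuse:::manifest_outcomes(ch$manifest, "OS")
  sub <- fit_both_submodels(ch, out)
  scores <- assemble_submodel_scores(ch, sub)
  scores$radiomic2 <- scores$radiomic
  fus1 <- fit_fusion(scores, out, "radiomic")
  fus2 <- fit_fusion(scores, out, c("radiomic", "radiomic2"))
  f1 <- predict_fused(fus1, scores)
  f2 <- predict_fused(fus2, scores)
  c1 <- harrell_c(f1$score, ch$manifest$os_months, ch$manifest$os_event)
  c2 <- harrell_c(f2$score, ch$manifest$os_months, ch$manifest$os_event)
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("independent informative modalities get positive coefficients", {
  signs <- 0
  for (seed in 1:10) {
    ch <- fusion_cohort(seed, n = 500)
    out <- mmfuse:::manifest_outcomes(ch$manifest, "OS")
    sub <- fit_both_submodels(ch, out)
    scores <- assemble_submodel_scores(ch, sub)
    fus <- fit_fusion(scores, out, c("radiomic", "histopathology"))
    if (all(fus$coef > 0)) signs <- signs + 1
  }
  expect_gte(signs, 9)
})

test_that("the fused score is the stated linear combination", {
  fus <- structure(
    list(modalities = c("radiomic", "histopathology"),
         coef = c(radiomic = 0.8, histopathology = 0.5),
         se = c(radiomic = 0.1, histopathology = 0.1),
         l2 = 0.5, n_intersection = 10L, n_events = 8L),
    class = "fusion_model"
  )
  scores <- tibble::tibble(id = c("a", "b", "c"),
                           radiomic = c(1, 0, NA),
                           histopathology = c(2, -1, 1))
  fused <- predict_fused(fus, scores)
  expect_equal(fused$score, c(-(0.8 * 1 + 0.5 * 2), -(0.8 * 0 + 0.5 * -1), NA))

  fus$coef[] <- 0
  expect_equal(predict_fused(fus, scores)$score[1:2], c(0, 0))
})

test_that("an empty intersection names the binding modality", {
  scores <- tibble::tibble(id = c("a", "b"), radiomic = c(1, NA),
                           histopathology = c(NA, 1))
  out <- tibble::tibble(id = c("a", "b"), time = c(3, 4), event = c(TRUE, TRUE))
  expect_error(fit_fusion(scores, out, c("radiomic", "histopathology")),
               "binding modality")
})

test_that("the fusion stage fits one coefficient per modality", {
  ch <- fusion_cohort(5, n = 300)
  out <- mmfuse:::manifest_outcomes(ch$manifest, "OS")
  sub <- fit_both_submodels(ch, out)
  scores <- assemble_submodel_scores(ch, sub)
  fus <- fit_fusion(scores, out, c("genomic", "radiomic", "histopathology"))
  expect_length(fus$coef, 3)
  expect_equal(glance(fus)$combo, "GRH")
})

test_that("complementary signals raise the fused test concordance", {
  gains_r <- numeric(0)
  gains_h <- numeric(0)
  for (seed in 1:8) {
    train <- fusion_cohort(seed, n = 600)
    test <- fusion_cohort(seed + 1000, n = 800)
    out_tr <- mmfuse:::manifest_outcomes(train$manifest, "OS")
    out_te <- mmfuse:::manifest_outcomes(test$manifest, "OS")
    sub <- fit_both_submodels(train, out_tr)
    sc_tr <- assemble_submodel_scores(train, sub)
    sc_te <- assemble_submodel_scores(test, sub)
    fus <- fit_fusion(sc_tr, out_tr, c("radiomic", "histopathology"))
    fused_te <- predict_fused(fus, sc_te)
    c_f <- harrell_c(fused_te$score, out_te$time, out_te$event)
    c_r <- harrell_c(-sc_te$radiomic, out_te$time, out_te$event)
    c_h <- harrell_c(-sc_te$histopathology, out_te$time, out_te$event)
    gains_r <- c(gains_r, c_f - c_r)
    gains_h <- c(gains_h, c_f - c_h)
  }
  expect_gte(mean(gains_r), 0.02)
  expect_gte(mean(gains_h), 0.02)
})

test_that("perfectly redundant signals give no fused advantage", {
  diffs <- numeric(0)
  for (seed in 1:5) {
    train <- fusion_cohort(seed, n = 600, cross_r = 0.999)
    test <- fusion_cohort(seed + 2000, n = 800, cross_r = 0.999)
    out_tr <- mmfuse:::manifest_outcomes(train$manifest, "OS")
    out_te <- mmfuse:::manifest_outcomes(test$manifest, "OS")
    sub <- fit_both_submodels(train, out_tr)
    sc_tr <- assemble_submodel_scores(train, sub)
    sc_te <- assemble_submodel_scores(test, sub)
    fus <- fit_fusion(sc_tr, out_tr, c("radiomic", "histopathology"))
    fused_te <- predict_fused(fus, sc_te)
    c_f <- harrell_c(fused_te$score, out_te$time, out_te$event)
    c_best <- max(harrell_c(-sc_te$radiomic, out_te$time, out_te$event),
                  harrell_c(-sc_te$histopathology, out_te$time, out_te$event))
    diffs <- c(diffs, c_f - c_best)
  }
  expect_lte(mean(diffs), 0.01)
})

test_that("a tiny cohort produces an ablation report without crashing", {
  ch <- fusion_cohort(9, n = 60,
                      availability = c(radiomic = 0.8, histopathology = 0.8))
  cfg <- pipeline_config(
    modalities = c("genomic", "radiomic", "histopathology"),
    combos = list("genomic", c("radiomic", "histopathology")),
    selection = list(radiomic = selection_config(min_events = 5),
                     histopathology = selection_config(min_events = 5)),
    n_test = 10, n_boot = 20, n_perm = 50, seed = 1
  )
  expect_no_error(suppressWarnings(suppressMessages(
    res <- ablation_full_information(ch, cfg)
  )))
  expect_true(is.data.frame(res))
})
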
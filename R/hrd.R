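# Rule-based HRD subtyping from genomic evidence.
#
# Two rule sets are implemented. Both consume pre-annotated evidence
# (variant significance comes from the input flags; no re-annotation):
#
# MSK-style panel rules: a patient with high-confidence dominant SBS3 or at
# least one significant variant or deep deletion in the HRD-DDR genes is
# HRD, except when there is evidence of the foldback-inversion or tandem
# duplicator subgroups (CCNE1 amplification or a CDK12 SNV), in which case
# conflicting evidence yields "ambiguous". Unsequenced patients are
# ambiguous; sequenced patients with no HRD evidence are HRP. Low-confidence
# SBS3 is never used. Send-out panels are HRP unless a provider-flagged
# significant variant is present.
#
# TCGA-style rules: at least one significant SNV or deep deletion in the
# HRD-DDR genes is HRD; a CDK12 SNV or CCNE1 amplification together with an
# HRD-DDR SNV is ambiguous; SBS3 frequency strictly greater than 15% without
# conflicting proficiency evidence is HRD; patients without SNV/CNA data are
# ambiguous; everyone else is HRP.
#
# CDK12 and CCNE1 act as dedicated subtype-exception markers and are kept
# out of the HRD-DDR evidence set, so that the exception clauses cannot be
# triggered by the same event that supplies the HRD evidence.

#' Default HRD-DDR gene panel
#'
#' Canonical homologous-recombination DNA-damage-response genes used as the
#' default evidence set. The panel is configurable per call; CDK12 and CCNE1
#' are deliberately excluded because they mark the tandem duplicator and
#' foldback-inversion subgroups handled by the exception clauses.
#'
#' @return A character vector of gene symbols.
#' @export
hrd_ddr_genes <- function() {
  c("BRCA1", "BRCA2", "PALB2", "RAD51B", "RAD51C", "RAD51D",
    "ATM", "BARD1", "BRIP1", "CHEK2", "FANCA")
}

#' Bundle genomic evidence for one patient
#'
#' @param variants Tibble with columns `gene`, `variant_class` (one of
#'   `"SNV"`, `"indel"`, `"deep_del"`, `"amp"`) and `oncogenic` (logical:
#'   flagged significant by the annotating provider).
#' @param sbs3_status One of `"high"`, `"low"`, `"absent"`, `"unknown"`:
#'   confidence that SBS3 is the dominant mutational signature.
#' @param sbs3_frequency SBS3 activity fraction in `[0, 1]`, or `NA`.
#' @param panel Sequencing context: `"full_panel"`, `"hrd_ddr_sendout"`, or
#'   `"none"`.
#' @param genes HRD-DDR gene panel; defaults to [hrd_ddr_genes()].
#' @return A `genomic_evidence` object.
#' @export
genomic_evidence <- function(variants = NULL,
                             sbs3_status = "unknown",
                             sbs3_frequency = NA_real_,
                             panel = c("full_panel", "hrd_ddr_sendout", "none"),
                             genes = hrd_ddr_genes()) {
  panel <- match.arg(panel)
  sbs3_status <- match.arg(sbs3_status, c("high", "low", "absent", "unknown"))
  if (is.null(variants)) {
    variants <- tibble(gene = character(), variant_class = character(),
                       oncogenic = logical())
  }
  variants <- as_tibble(variants)
  stopifnot(all(c("gene", "variant_class", "oncogenic") %in% names(variants)))
  bad <- setdiff(variants$variant_class, c("SNV", "indel", "deep_del", "amp"))
  if (length(bad) > 0) {
    abort(paste0("unknown variant class: ", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(variants$gene))) abort("empty gene symbol in variants")
  if (!is.na(sbs3_frequency) && (sbs3_frequency < 0 || sbs3_frequency > 1)) {
    abort("`sbs3_frequency` must be in [0, 1]")
  }
  structure(
    list(variants = variants, sbs3_status = sbs3_status,
         sbs3_frequency = sbs3_frequency, panel = panel, genes = genes),
    class = "genomic_evidence"
  )
}

new_hrd_call <- function(subtype, rationale) {
  stopifnot(subtype %in% c("HRD", "HRP", "ambiguous"), length(rationale) > 0)
  structure(list(subtype = subtype, rationale = rationale), class = "hrd_call")
}

#' @export
print.hrd_call <- function(x, ...) {
  cat("<hrd_call>", x$subtype, "\n")
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}

# evidence predicates -------------------------------------------------------

ev_ddr_hit <- function(ev, classes = c("SNV", "indel", "deep_del")) {
  v <- ev$variants
  any(v$gene %in% ev$genes & v$variant_class %in% classes & v$oncogenic)
}

ev_ddr_snv <- function(ev) {
  v <- ev$variants
  any(v$gene %in% ev$genes & v$variant_class == "SNV" & v$oncogenic)
}

ev_ccne1_amp <- function(ev) {
  v <- ev$variants
  any(v$gene == "CCNE1" & v$variant_class == "amp")
}

ev_cdk12_snv <- function(ev) {
  v <- ev$variants
  any(v$gene == "CDK12" & v$variant_class == "SNV")
}

#' Call HRD status under the panel-sequencing (MSK-style) rule set
#'
#' @param evidence A [genomic_evidence()] object.
#' @return An `hrd_call` with a machine-readable rule trace.
#' @export
call_hrd_msk <- function(evidence) {
  stopifnot(inherits(evidence, "genomic_evidence"))
  ev <- evidence
  if (ev$panel == "none") {
    return(new_hrd_call("ambiguous", "no sequencing available"))
  }

  trace <- character()
  if (ev$panel == "hrd_ddr_sendout") {
    # send-out panels: provider-flagged significant variant drives the call
    hrd_evidence <- any(ev$variants$oncogenic)
    trace <- c(trace, if (hrd_evidence) {
      "send-out panel: variant of known significance reported"
    } else {
      "send-out panel: no variant of known significance"
    })
  } else {
    sig3 <- ev$sbs3_status == "high"
    ddr <- ev_ddr_hit(ev)
    hrd_evidence <- sig3 || ddr
    if (sig3) trace <- c(trace, "high-confidence dominant SBS3")
    if (ev$sbs3_status == "low") {
      trace <- c(trace, "low-confidence SBS3 not used")
    }
    if (ddr) trace <- c(trace, "significant variant or deep deletion in HRD-DDR genes")
  }

  exception <- ev_ccne1_amp(ev) || ev_cdk12_snv(ev)
  if (exception) {
    marker <- c(if (ev_ccne1_amp(ev)) "CCNE1 amplification",
                if (ev_cdk12_snv(ev)) "CDK12 SNV")
    trace <- c(trace, paste0("subtype-exception marker: ",
                             paste(marker, collapse = " and ")))
  }

  if (hrd_evidence && exception) {
    return(new_hrd_call("ambiguous", c(trace, "conflicting evidence")))
  }
  if (hrd_evidence) {
    return(new_hrd_call("HRD", trace))
  }
  new_hrd_call("HRP", c(trace, "sequenced without HRD evidence"))
}

#' Call HRD status under the exome/array (TCGA-style) rule set
#'
#' @inheritParams call_hrd_msk
#' @export
call_hrd_tcga <- function(evidence) {
  stopifnot(inherits(evidence, "genomic_evidence"))
  ev <- evidence
  if (ev$panel == "none") {
    return(new_hrd_call("ambiguous", "no SNV/CNA data available"))
  }

  trace <- character()
  exception <- ev_ccne1_amp(ev) || ev_cdk12_snv(ev)
  if (exception) {
    marker <- c(if (ev_ccne1_amp(ev)) "CCNE1 amplification",
                if (ev_cdk12_snv(ev)) "CDK12 SNV")
    trace <- c(trace, paste0("subtype-exception marker: ",
                             paste(marker, collapse = " and ")))
  }

  # conflict clause: exception marker together with an HRD-DDR SNV
  if (exception && ev_ddr_snv(ev)) {
    return(new_hrd_call("ambiguous",
                        c(trace, "HRD-DDR SNV with exception marker: conflicting evidence")))
  }
  if (ev_ddr_hit(ev)) {
    return(new_hrd_call("HRD", c(trace, "significant SNV or deep deletion in HRD-DDR genes")))
  }
  sbs3_high <- !is.na(ev$sbs3_frequency) && ev$sbs3_frequency > 0.15
  if (sbs3_high && exception) {
    return(new_hrd_call("ambiguous",
                        c(trace, "SBS3 frequency > 15% with conflicting proficiency evidence")))
  }
  if (sbs3_high) {
    return(new_hrd_call("HRD", c(trace, "SBS3 frequency > 15%")))
  }
  new_hrd_call("HRP", c(trace, "no HRD evidence"))
}

#' Call HRD status for one patient under a chosen rule set
#'
#' @inheritParams call_hrd_msk
#' @param ruleset `"msk"` or `"tcga"`; never auto-detected.
#' @export
call_hrd <- function(evidence, ruleset = c("msk", "tcga")) {
  switch(match.arg(ruleset), msk = call_hrd_msk(evidence),
         tcga = call_hrd_tcga(evidence))
}

#' Map an HRD call to the genomic risk score
#'
#' Proficient (HRP) tumors are designated high risk (1.0) and deficient
#' (HRD) tumors low risk (0.0); ambiguous calls yield a missing score and
#' the patient is excluded from genomic-model analyses.
#'
#' @param call An `hrd_call`, or a character vector of subtypes.
#' @return Numeric risk score(s); `NA` for ambiguous.
#' @export
genomic_risk <- function(call) {
  subtype <- if (inherits(call, "hrd_call")) call$subtype else call
  unname(c(HRD = 0, HRP = 1, ambiguous = NA_real_)[subtype])
}

#' Call HRD status for a table of patients
#'
#' Data-frame front end over [call_hrd()]: joins MAF-like variant rows,
#' copy-number calls and signature annotations by patient and returns one
#' call per patient.
#'
#' @param patients Tibble with columns `patient_id` and `panel`.
#' @param variants Tibble with columns `patient_id`, `gene`, `variant_class`,
#'   `oncogenic` (MAF-like rows; copy-number calls use classes `"amp"` /
#'   `"deep_del"`).
#' @param signatures Tibble with columns `patient_id`, `sbs3_status`,
#'   `sbs3_frequency`; patients absent from it get status `"unknown"`.
#' @param ruleset `"msk"` or `"tcga"`.
#' @param genes HRD-DDR gene panel.
#' @return Tibble with `patient_id`, `subtype`, `risk`, `rationale`.
#' @export
call_hrd_cohort <- function(patients, variants = NULL, signatures = NULL,
                            ruleset = c("msk", "tcga"), genes = hrd_ddr_genes()) {
  ruleset <- match.arg(ruleset)
  stopifnot(all(c("patient_id", "panel") %in% names(patients)))
  rows <- map(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    v <- if (!is.null(variants)) {
      dplyr::filter(variants, .data$patient_id == pid)[
        , c("gene", "variant_class", "oncogenic")]
    }
    s <- if (!is.null(signatures)) {
      dplyr::filter(signatures, .data$patient_id == pid)
    }
    ev <- genomic_evidence(
      variants = v,
      sbs3_status = if (!is.null(s) && nrow(s) > 0) s$sbs3_status[1] else "unknown",
      sbs3_frequency = if (!is.null(s) && nrow(s) > 0) s$sbs3_frequency[1] else NA_real_,
      panel = patients$panel[i],
      genes = genes
    )
    call <- call_hrd(ev, ruleset)
    tibble(patient_id = pid, subtype = call$subtype,
           risk = genomic_risk(call),
           rationale = paste(call$rationale, collapse = "; "))
  })
  bind_rows(rows)
}
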
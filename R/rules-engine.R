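## Criterion evaluation. Each assess_* operation evaluates one family
## of criteria on an annotated variant under a scheme and returns
## rule_result objects tagged with their evidence channel. run_rules()
## assembles the complete, deterministically ordered result list.

fmt <- function(x) formatC(x, format = "g", digits = 6)

rr <- function(code, channel, status, strength = NULL, comment = "") {
  rule_result(code, channel, status, strength, comment)
}

disabled <- function(code, channel, why) {
  rr(code, channel, "disabled_by_scheme", comment = why)
}

## Strongest strength whose cut is reached. `cuts` is a named list in
## pathogenic or benign direction; `cmp` is `>=` for pathogenic-style
## cuts and `<=` for benign-style cuts.
graded_strength <- function(score, cuts, cmp) {
  best <- NULL
  for (s in c("supporting", "moderate", "strong", "very_strong")) {
    cut <- cuts[[s]]
    if (!is.null(cut) && cmp(score, cut)) best <- s
  }
  best
}

#' Population-frequency criteria: BA1, BS1, BS2, PM2
#'
#' BA1 (stand-alone) applies above the `ba1_af` cut, BS1 (strong)
#' between `bs1_af` and `ba1_af`, PM2 (supporting by default, the
#' downgraded strength) when the variant is absent or rarer than
#' `pm2_af` at adequate coverage.  BS2 uses the count of observations
#' in a cancer-free aged-women resource and is disabled under schemes
#' whose guidelines do not admit that resource.
#'
#' @param variant An [annotated_variant()].
#' @param scheme A `scheme_config`.
#' @return List of [rule_result()] (channel `general`).
#' @export
assess_population <- function(variant, scheme) {
  pop <- variant$pop
  th <- scheme$thresholds
  out <- list()
  af <- pop$popmax_af

  if (!pop$coverage_ok) {
    for (code in c("BA1", "BS1", "PM2"))
      out[[code]] <- rr(code, "general", "not_evaluable",
                        comment = "position not adequately covered in the population resource")
  } else if (is.null(af)) {
    out$BA1 <- rr("BA1", "general", "not_applied",
                  comment = "variant absent from the population resource")
    out$BS1 <- rr("BS1", "general", "not_applied",
                  comment = "variant absent from the population resource")
    out$PM2 <- rr("PM2", "general", "applied",
                  strength = scheme$rule_defaults$pm2_strength,
                  comment = sprintf("variant absent (allele count %d) at adequate coverage; below PM2 cutoff %s",
                                    pop$allele_count, fmt(th$pm2_af)))
  } else {
    out$BA1 <- if (af > th$ba1_af)
      rr("BA1", "general", "applied", strength = "stand_alone",
         comment = sprintf("popmax AF %s exceeds BA1 cutoff %s",
                           fmt(af), fmt(th$ba1_af)))
    else rr("BA1", "general", "not_applied",
            comment = sprintf("popmax AF %s at or below BA1 cutoff %s",
                              fmt(af), fmt(th$ba1_af)))
    out$BS1 <- if (af > th$bs1_af && af <= th$ba1_af)
      rr("BS1", "general", "applied", strength = "strong",
         comment = sprintf("popmax AF %s above BS1 cutoff %s",
                           fmt(af), fmt(th$bs1_af)))
    else rr("BS1", "general", "not_applied",
            comment = sprintf("popmax AF %s outside the BS1 band (%s, %s]",
                              fmt(af), fmt(th$bs1_af), fmt(th$ba1_af)))
    out$PM2 <- if (af < th$pm2_af)
      rr("PM2", "general", "applied",
         strength = scheme$rule_defaults$pm2_strength,
         comment = sprintf("popmax AF %s below PM2 cutoff %s",
                           fmt(af), fmt(th$pm2_af)))
    else rr("PM2", "general", "not_applied",
            comment = sprintf("popmax AF %s at or above PM2 cutoff %s",
                              fmt(af), fmt(th$pm2_af)))
  }

  out$BS2 <- if (!scheme$bs2_allowed) {
    disabled("BS2", "general",
             sprintf("BS2 is not available under the %s scheme (healthy-observation resource not admitted)",
                     scheme$scheme_id))
  } else if (is.null(pop$flossies_count)) {
    rr("BS2", "general", "not_evaluable",
       comment = "missing: flossies_count")
  } else if (pop$flossies_count >= th$bs2_count_min) {
    rr("BS2", "general", "applied",
       strength = scheme$rule_defaults$bs2_strength,
       comment = sprintf("%d observations in cancer-free aged women (cutoff %d)",
                         pop$flossies_count, th$bs2_count_min))
  } else {
    rr("BS2", "general", "not_applied",
       comment = sprintf("%d observations below the BS2 cutoff %d",
                         pop$flossies_count, th$bs2_count_min))
  }
  out
}

#' Computational-prediction criteria: PP3, BP4 (both channels), BP7
#'
#' The protein channel grades the scheme's single pathogenicity
#' predictor (REVEL or BayesDel) against its calibrated strength cuts;
#' the splicing channel applies the SpliceAI maximum delta score
#' against a single pathogenic/benign cut pair.  BP7 (splicing)
#' requires a synonymous (or, per configuration, non-canonical
#' intronic) variant with a benign splicing prediction and no RNA
#' confirmation of aberrant splicing.
#'
#' @inheritParams assess_population
#' @export
assess_computational <- function(variant, scheme) {
  th <- scheme$thresholds
  sc <- variant$scores
  tool <- scheme$pathogenicity_tool
  score <- sc[[tool]]
  out <- list()

  if (is.null(score)) {
    out$PP3_protein <- rr("PP3", "protein", "not_evaluable",
                          comment = sprintf("missing: %s score", tool))
    out$BP4_protein <- rr("BP4", "protein", "not_evaluable",
                          comment = sprintf("missing: %s score", tool))
  } else {
    ps <- graded_strength(score, th$patho_cuts, `>=`)
    bs <- graded_strength(score, th$patho_benign_cuts, `<=`)
    out$PP3_protein <- if (!is.null(ps))
      rr("PP3", "protein", "applied", strength = ps,
         comment = sprintf("%s score %s reaches the %s pathogenic cut %s",
                           tool, fmt(score), ps, fmt(th$patho_cuts[[ps]])))
    else rr("PP3", "protein", "not_applied",
            comment = sprintf("%s score %s below the supporting pathogenic cut %s",
                              tool, fmt(score),
                              fmt(th$patho_cuts$supporting)))
    out$BP4_protein <- if (!is.null(bs))
      rr("BP4", "protein", "applied", strength = bs,
         comment = sprintf("%s score %s reaches the %s benign cut %s",
                           tool, fmt(score), bs,
                           fmt(th$patho_benign_cuts[[bs]])))
    else rr("BP4", "protein", "not_applied",
            comment = sprintf("%s score %s above the supporting benign cut %s",
                              tool, fmt(score),
                              fmt(th$patho_benign_cuts$supporting)))
  }

  delta <- sc$spliceai_max_delta
  if (is.null(delta)) {
    for (code in c("PP3", "BP4", "BP7"))
      out[[paste0(code, "_splicing")]] <-
        rr(code, "splicing", "not_evaluable",
           comment = "missing: spliceai_max_delta")
  } else {
    out$PP3_splicing <- if (delta >= th$spliceai_pathogenic)
      rr("PP3", "splicing", "applied",
         strength = scheme$rule_defaults$spliceai_pp3_strength,
         comment = sprintf("SpliceAI delta %s at or above the pathogenic cut %s",
                           fmt(delta), fmt(th$spliceai_pathogenic)))
    else rr("PP3", "splicing", "not_applied",
            comment = sprintf("SpliceAI delta %s below the pathogenic cut %s",
                              fmt(delta), fmt(th$spliceai_pathogenic)))
    out$BP4_splicing <- if (delta <= th$spliceai_benign)
      rr("BP4", "splicing", "applied",
         strength = scheme$rule_defaults$spliceai_bp4_strength,
         comment = sprintf("SpliceAI delta %s at or below the benign cut %s",
                           fmt(delta), fmt(th$spliceai_benign)))
    else rr("BP4", "splicing", "not_applied",
            comment = sprintf("SpliceAI delta %s above the benign cut %s",
                              fmt(delta), fmt(th$spliceai_benign)))

    csq <- variant$tx$consequence
    bp7_type <- csq == "synonymous" ||
      (csq == "intronic" && isTRUE(scheme$rule_defaults$bp7_intronic_allowed))
    canonical <- csq %in% c("splice_donor", "splice_acceptor")
    out$BP7_splicing <- if (!bp7_type || canonical) {
      rr("BP7", "splicing", "not_applied",
         comment = sprintf("consequence %s outside BP7 scope", csq))
    } else if (variant$rna$status == "confirmed_aberrant") {
      rr("BP7", "splicing", "not_applied",
         comment = "RNA data confirms aberrant splicing")
    } else if (delta <= th$spliceai_benign) {
      rr("BP7", "splicing", "applied", strength = "supporting",
         comment = sprintf("%s variant with SpliceAI delta %s at or below the benign cut %s",
                           csq, fmt(delta), fmt(th$spliceai_benign)))
    } else {
      rr("BP7", "splicing", "not_applied",
         comment = sprintf("SpliceAI delta %s above the benign cut %s",
                           fmt(delta), fmt(th$spliceai_benign)))
    }
  }
  out
}

#' Loss-of-function criterion PVS1 (protein and splicing channels)
#'
#' Protein channel for premature-termination/frameshift and start-loss
#' variants, graded by the NMD rule (PTC more than 50 nt upstream of
#' the last exon-exon junction and outside the last exon is
#' NMD-competent), critical-domain overlap, and the fraction of protein
#' removed.  Splicing channel for canonical +/-1/2 variants, graded by
#' the precomputed frame/NMD call for the predicted aberrant
#' transcript.  For schemes with RNA integration (BRCA1/BRCA2),
#' confirmed normal splicing forces the splicing channel to
#' `not_applied`, and confirmed aberrant splicing pins the predicted
#' event as observed.
#'
#' @inheritParams assess_population
#' @export
assess_pvs1 <- function(variant, scheme) {
  tx <- variant$tx
  prior <- variant$prior
  csq <- tx$consequence
  out <- list()

  ## --- protein channel ---
  if (csq %in% c("nonsense", "frameshift")) {
    missing <- c(
      if (is.null(tx$last_junction_offset) && !tx$is_last_exon)
        "last_junction_offset",
      if (is.null(tx$protein_length)) "protein_length",
      if (is.null(tx$ptc_position)) "ptc_position")
    if (length(missing)) {
      out$protein <- rr("PVS1", "protein", "not_evaluable",
                        comment = paste("missing:",
                                        paste(missing, collapse = ", ")))
    } else {
      nmd <- !tx$is_last_exon && tx$last_junction_offset <= -50
      if (nmd) {
        out$protein <- rr("PVS1", "protein", "applied",
                          strength = "very_strong",
                          comment = sprintf("%s with NMD-competent PTC (offset %d nt from the last junction)",
                                            csq, tx$last_junction_offset))
      } else if (prior$domain_overlap) {
        out$protein <- rr("PVS1", "protein", "applied", strength = "strong",
                          comment = sprintf("%s escaping NMD but truncating a functionally critical region (PTC codon %d)",
                                            csq, tx$ptc_position))
      } else if ((tx$protein_length - tx$ptc_position) / tx$protein_length
                 > 0.10) {
        out$protein <- rr("PVS1", "protein", "applied", strength = "strong",
                          comment = sprintf("%s escaping NMD, removing %s%% of the protein (PTC codon %d of %d)",
                                            csq,
                                            fmt(100 * (tx$protein_length - tx$ptc_position) / tx$protein_length),
                                            tx$ptc_position, tx$protein_length))
      } else {
        out$protein <- rr("PVS1", "protein", "applied",
                          strength = "moderate",
                          comment = sprintf("%s escaping NMD, removing <= 10%% of the protein (PTC codon %d of %d)",
                                            csq, tx$ptc_position,
                                            tx$protein_length))
      }
    }
  } else if (csq == "start_lost") {
    if (isTRUE(scheme$rule_defaults$start_lost_alternative_start)) {
      out$protein <- rr("PVS1", "protein", "applied",
                        strength = "supporting",
                        comment = "start-loss with an annotated alternative in-frame start")
    } else {
      out$protein <- rr("PVS1", "protein", "applied", strength = "moderate",
                        comment = "start-loss without an annotated alternative in-frame start")
    }
  } else {
    out$protein <- rr("PVS1", "protein", "not_applied",
                      comment = sprintf("consequence %s outside the protein loss-of-function tree",
                                        csq))
  }

  ## --- splicing channel ---
  if (csq %in% c("splice_donor", "splice_acceptor")) {
    if (scheme$rna_integration &&
        variant$rna$status == "confirmed_normal_splicing") {
      out$splicing <- rr("PVS1", "splicing", "not_applied",
                         comment = "RNA evidence confirms normal splicing; predicted loss-of-function overruled")
    } else {
      missing <- c(if (is.null(tx$splice_frame_disrupting))
        "splice_frame_disrupting")
      if (is.null(tx$splice_frame_disrupting)) {
        out$splicing <- rr("PVS1", "splicing", "not_evaluable",
                           comment = paste("missing:",
                                           paste(missing, collapse = ", ")))
      } else if (tx$splice_frame_disrupting &&
                 is.null(tx$splice_nmd)) {
        out$splicing <- rr("PVS1", "splicing", "not_evaluable",
                           comment = "missing: splice_nmd")
      } else {
        observed <- scheme$rna_integration &&
          variant$rna$status == "confirmed_aberrant"
        tag <- if (observed) "RNA-confirmed" else "predicted"
        site <- sprintf("%s %+d", csq, tx$dist_to_splice_site)
        if (tx$splice_frame_disrupting && isTRUE(tx$splice_nmd)) {
          out$splicing <- rr("PVS1", "splicing", "applied",
                             strength = "very_strong",
                             comment = sprintf("%s: %s frame-disrupting event with NMD", site, tag))
        } else if (tx$splice_frame_disrupting && prior$domain_overlap) {
          out$splicing <- rr("PVS1", "splicing", "applied",
                             strength = "strong",
                             comment = sprintf("%s: %s frame-disrupting event escaping NMD in a critical region", site, tag))
        } else if (!tx$splice_frame_disrupting && prior$domain_overlap) {
          out$splicing <- rr("PVS1", "splicing", "applied",
                             strength = "strong",
                             comment = sprintf("%s: %s in-frame loss overlapping a critical region", site, tag))
        } else {
          out$splicing <- rr("PVS1", "splicing", "applied",
                             strength = "moderate",
                             comment = sprintf("%s: %s event without critical-region involvement", site, tag))
        }
      }
    }
  } else {
    out$splicing <- rr("PVS1", "splicing", "not_applied",
                       comment = sprintf("consequence %s is not a canonical splice-site variant",
                                         csq))
  }
  out
}

#' Same-change criteria: PS1 (protein and splicing), PM5 (protein)
#'
#' PS1 (protein, strong) requires an established pathogenic variant
#' with the identical amino-acid change and no indication that this
#' variant acts through splicing.  PS1 (splicing, default moderate)
#' requires an established pathogenic variant at the same splice site
#' with a comparable predicted event supported by the splicing
#' predictor.  PM5 (moderate) requires an established pathogenic
#' missense at the same codon with a different substitution.
#'
#' @inheritParams assess_population
#' @export
assess_same_change <- function(variant, scheme) {
  th <- scheme$thresholds
  prior <- variant$prior
  csq <- variant$tx$consequence
  delta <- variant$scores$spliceai_max_delta
  out <- list()

  spliceogenic <- !is.null(delta) && delta >= th$spliceai_pathogenic
  out$PS1_protein <- if (prior$same_aa_change && csq == "missense" &&
                         !spliceogenic)
    rr("PS1", "protein", "applied", strength = "strong",
       comment = "established pathogenic variant with the identical amino-acid change; no splicing-mediated mechanism indicated")
  else if (prior$same_aa_change && csq == "missense" && spliceogenic)
    rr("PS1", "protein", "not_applied",
       comment = sprintf("identical amino-acid change known, but SpliceAI delta %s indicates a splicing mechanism",
                         fmt(delta)))
  else rr("PS1", "protein", "not_applied",
          comment = "no established pathogenic variant with the identical amino-acid change")

  out$PS1_splicing <- if (prior$same_splice_site_pathogenic &&
                          !is.null(delta) &&
                          delta >= th$spliceai_pathogenic)
    rr("PS1", "splicing", "applied",
       strength = scheme$rule_defaults$ps1_splicing_strength,
       comment = sprintf("established pathogenic variant at the same splice site; SpliceAI delta %s supports a comparable event",
                         fmt(delta)))
  else if (prior$same_splice_site_pathogenic && is.null(delta))
    rr("PS1", "splicing", "not_evaluable",
       comment = "missing: spliceai_max_delta")
  else rr("PS1", "splicing", "not_applied",
          comment = "no comparable established pathogenic splice-site variant")

  out$PM5_protein <- if (prior$same_codon_other_aa && csq == "missense" &&
                         !prior$same_aa_change)
    rr("PM5", "protein", "applied", strength = "moderate",
       comment = "established pathogenic missense at the same residue with a different substitution")
  else rr("PM5", "protein", "not_applied",
          comment = "no established pathogenic missense at the same residue (or identical change already covered by PS1)")
  out
}

#' Structural/region criteria: PM1, PM4, BP3, PP2, BP1
#'
#' All protein channel.  PM1 from hotspot overlap; PM4 for in-frame
#' indels outside repeat regions and stop-loss; BP3 for in-frame
#' indels inside functionless repeats (base scheme only -- no
#' gene-specific guideline admits BP3); PP2 and BP1 from the scheme's
#' gene-mechanism flags.
#'
#' @inheritParams assess_population
#' @export
assess_structural <- function(variant, scheme) {
  prior <- variant$prior
  csq <- variant$tx$consequence
  out <- list()

  out$PM1 <- if (prior$hotspot_overlap)
    rr("PM1", "protein", "applied", strength = "moderate",
       comment = "variant overlaps a mutational hotspot (hotspot_overlap = TRUE)")
  else rr("PM1", "protein", "not_applied",
          comment = "no hotspot overlap")

  out$PM4 <- if ((csq == "inframe_indel" && !prior$repeat_region) ||
                 csq == "stop_lost")
    rr("PM4", "protein", "applied", strength = "moderate",
       comment = sprintf("protein-length change: %s%s", csq,
                         if (csq == "inframe_indel")
                           " outside a repeat region" else ""))
  else rr("PM4", "protein", "not_applied",
          comment = sprintf("consequence %s does not alter protein length outside repeats",
                            csq))

  out$BP3 <- if (!scheme$bp3_applicable)
    disabled("BP3", "protein",
             sprintf("BP3 is not applicable under the %s scheme",
                     scheme$scheme_id))
  else if (csq == "inframe_indel" && prior$repeat_region)
    rr("BP3", "protein", "applied", strength = "supporting",
       comment = "in-frame indel in a repetitive region without known function (repeat_region = TRUE)")
  else rr("BP3", "protein", "not_applied",
          comment = "not an in-frame indel in a functionless repeat")

  out$PP2 <- if (csq == "missense" && scheme$missense_constrained)
    rr("PP2", "protein", "applied", strength = "supporting",
       comment = sprintf("missense variant in a missense-constrained gene (%s scheme)",
                         scheme$scheme_id))
  else rr("PP2", "protein", "not_applied",
          comment = "not a missense variant in a missense-constrained gene")

  out$BP1 <- if (csq == "missense" && scheme$truncating_mechanism)
    rr("BP1", "protein", "applied", strength = "supporting",
       comment = sprintf("missense variant in a gene with a truncating disease mechanism (%s scheme)",
                         scheme$scheme_id))
  else rr("BP1", "protein", "not_applied",
          comment = "not a missense variant in a truncating-mechanism gene")
  out
}

#' Functional-assay criteria: PS3, BS3
#'
#' Automated only under schemes with curated assay data (BRCA1/BRCA2);
#' applied at the validated strength of the assay.
#'
#' @inheritParams assess_population
#' @export
assess_functional <- function(variant, scheme) {
  assay <- variant$assay
  out <- list()
  if (!scheme$functional_rules_allowed) {
    why <- sprintf("functional-assay criteria are not automated under the %s scheme",
                   scheme$scheme_id)
    out$PS3 <- disabled("PS3", "general", why)
    out$BS3 <- disabled("BS3", "general", why)
    return(out)
  }
  if (assay$status == "absent") {
    out$PS3 <- rr("PS3", "general", "not_evaluable",
                  comment = "missing: functional assay result")
    out$BS3 <- rr("BS3", "general", "not_evaluable",
                  comment = "missing: functional assay result")
    return(out)
  }
  out$PS3 <- if (assay$status == "non_functional")
    rr("PS3", "general", "applied", strength = assay$assay_strength,
       comment = sprintf("validated assay reports non-functional protein (assay strength %s)",
                         assay$assay_strength))
  else rr("PS3", "general", "not_applied",
          comment = sprintf("assay status %s does not demonstrate a damaging effect",
                            assay$status))
  out$BS3 <- if (assay$status == "functional")
    rr("BS3", "general", "applied", strength = assay$assay_strength,
       comment = sprintf("validated assay reports functional protein (assay strength %s)",
                         assay$assay_strength))
  else rr("BS3", "general", "not_applied",
          comment = sprintf("assay status %s does not demonstrate a neutral effect",
                            assay$status))
  out
}

#' Cosegregation criteria: PP1, BS4
#'
#' PP1 applies at the strongest strength whose likelihood-ratio cut the
#' cosegregation LR reaches (or, when only a count of informative
#' meioses is available, whose meioses cut it reaches); BS4 applies
#' analogously for LRs below the benign cuts.  Contradictory LR and
#' meioses evidence renders both not evaluable.
#'
#' @inheritParams assess_population
#' @export
assess_cosegregation <- function(variant, scheme) {
  th <- scheme$thresholds
  lr <- variant$coseg$likelihood_ratio
  meio <- variant$coseg$informative_meioses
  out <- list()

  if (is.null(lr) && is.null(meio)) {
    out$PP1 <- rr("PP1", "general", "not_evaluable",
                  comment = "missing: likelihood_ratio, informative_meioses")
    out$BS4 <- rr("BS4", "general", "not_evaluable",
                  comment = "missing: likelihood_ratio, informative_meioses")
    return(out)
  }
  if (!is.null(lr) && !is.null(meio)) {
    lr_benign <- lr <= th$bs4_lr_cuts$supporting
    meio_patho <- meio >= th$pp1_meioses_cuts$supporting
    if (lr_benign && meio_patho) {
      why <- sprintf("contradictory cosegregation evidence: LR %s indicates lack of segregation while %d informative meioses indicate cosegregation",
                     fmt(lr), meio)
      out$PP1 <- rr("PP1", "general", "not_evaluable", comment = why)
      out$BS4 <- rr("BS4", "general", "not_evaluable", comment = why)
      return(out)
    }
  }

  if (!is.null(lr)) {
    ps <- graded_strength(lr, th$pp1_lr_cuts, `>=`)
    bs <- graded_strength(lr, th$bs4_lr_cuts, `<=`)
    out$PP1 <- if (!is.null(ps))
      rr("PP1", "general", "applied", strength = ps,
         comment = sprintf("cosegregation LR %s reaches the %s cut %s",
                           fmt(lr), ps, fmt(th$pp1_lr_cuts[[ps]])))
    else rr("PP1", "general", "not_applied",
            comment = sprintf("cosegregation LR %s below the supporting cut %s",
                              fmt(lr), fmt(th$pp1_lr_cuts$supporting)))
    out$BS4 <- if (!is.null(bs))
      rr("BS4", "general", "applied", strength = bs,
         comment = sprintf("cosegregation LR %s at or below the %s benign cut %s",
                           fmt(lr), bs, fmt(th$bs4_lr_cuts[[bs]])))
    else rr("BS4", "general", "not_applied",
            comment = sprintf("cosegregation LR %s above the supporting benign cut %s",
                              fmt(lr), fmt(th$bs4_lr_cuts$supporting)))
  } else {
    ps <- graded_strength(meio, th$pp1_meioses_cuts, `>=`)
    out$PP1 <- if (!is.null(ps))
      rr("PP1", "general", "applied", strength = ps,
         comment = sprintf("%d informative meioses reach the %s cut %d",
                           meio, ps, th$pp1_meioses_cuts[[ps]]))
    else rr("PP1", "general", "not_applied",
            comment = sprintf("%d informative meioses below the supporting cut %d",
                              meio, th$pp1_meioses_cuts$supporting))
    out$BS4 <- rr("BS4", "general", "not_evaluable",
                  comment = "missing: likelihood_ratio (meioses counts carry no benign evidence)")
  }
  out
}

## Deterministic report order: pathogenic codes then benign, each in
## conventional ACMG order, channels general -> protein -> splicing.
result_order <- function() {
  rows <- list()
  for (code in automated_codes())
    for (ch in intersect(hc_channels(), rule_channels(code)))
      rows[[length(rows) + 1L]] <- c(code, ch)
  do.call(rbind, rows)
}

#' Evaluate every registered criterion on a variant
#'
#' Produces exactly one [rule_result()] per automated criterion and
#' defined channel, in deterministic order.  Criteria outside the
#' scheme's enabled set (or gated off by the scheme) report
#' `disabled_by_scheme`; criteria lacking required inputs report
#' `not_evaluable` with the missing fields named.
#'
#' @inheritParams assess_population
#' @return List of [rule_result()].
#' @export
run_rules <- function(variant, scheme) {
  stopifnot(inherits(variant, "annotated_variant"),
            inherits(scheme, "scheme_config"))
  pool <- c(assess_population(variant, scheme),
            assess_computational(variant, scheme),
            assess_pvs1_named(variant, scheme),
            assess_same_change(variant, scheme),
            assess_structural(variant, scheme),
            assess_functional(variant, scheme),
            assess_cosegregation(variant, scheme))
  keyed <- list()
  for (res in pool) keyed[[paste(res$code, res$channel, sep = ".")]] <- res

  ord <- result_order()
  out <- vector("list", nrow(ord))
  for (i in seq_len(nrow(ord))) {
    code <- ord[i, 1]; ch <- ord[i, 2]
    if (!code %in% scheme$enabled_rules) {
      out[[i]] <- disabled(code, ch,
                           sprintf("%s is outside the enabled rule set of the %s scheme",
                                   code, scheme$scheme_id))
      next
    }
    res <- keyed[[paste(code, ch, sep = ".")]]
    if (is.null(res))
      res <- rr(code, ch, "not_evaluable",
                comment = "no implementation produced a result")
    out[[i]] <- res
  }
  out
}

assess_pvs1_named <- function(variant, scheme) {
  r <- assess_pvs1(variant, scheme)
  list(PVS1_protein = r$protein, PVS1_splicing = r$splicing)
}

#' Tabulate a rule-result list
#'
#' @param results List of [rule_result()] from [run_rules()].
#' @return Data frame with columns `code`, `channel`, `status`,
#'   `strength`, `comment`.
#' @export
results_table <- function(results) {
  data.frame(
    code = vapply(results, `[[`, "", "code"),
    channel = vapply(results, `[[`, "", "channel"),
    status = vapply(results, `[[`, "", "status"),
    strength = vapply(results, function(r) r$strength %||% NA_character_,
                      ""),
    comment = vapply(results, `[[`, "", "comment"),
    stringsAsFactors = FALSE)
}
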
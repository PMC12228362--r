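## Independent straight-line expectation oracle.
##
## Re-derives, for a given annotated variant and scheme, the status and
## strength of every criterion, the per-channel classes under both
## systems, and the merged final class -- without calling any engine
## code (assess_*, run_rules, channel_select, classify_* or
## merge_channels).  Written as flat conditionals so fixture
## expectations and engine results are produced by two disjoint code
## paths; the end-to-end replay test compares them.

oracle_status <- function(status, strength = NA_character_) {
  list(status = status, strength = strength)
}

#' Straight-line expectation oracle for one variant
#'
#' @param av An [annotated_variant()].
#' @param scheme A `scheme_config`.
#' @return List with `rules` (named by `code.channel`, each a list with
#'   `status` and `strength`), `protein` and `splicing` (each with
#'   `acmg_class`, `point_score`, `point_class`), and `final_class`
#'   (merge of the point classes).
#' @export
oracle_expectations <- function(av, scheme) {
  th <- scheme$thresholds
  rd <- scheme$rule_defaults
  tx <- av$tx
  pop <- av$pop
  sc <- av$scores
  pr <- av$prior
  csq <- tx$consequence
  S <- oracle_status
  E <- list()

  enabled <- function(code) code %in% scheme$enabled_rules

  ## ---- population ----
  if (!enabled("BA1")) E[["BA1.general"]] <- S("disabled_by_scheme")
  else if (!pop$coverage_ok) E[["BA1.general"]] <- S("not_evaluable")
  else if (is.null(pop$popmax_af)) E[["BA1.general"]] <- S("not_applied")
  else if (pop$popmax_af > th$ba1_af)
    E[["BA1.general"]] <- S("applied", "stand_alone")
  else E[["BA1.general"]] <- S("not_applied")

  if (!enabled("BS1")) E[["BS1.general"]] <- S("disabled_by_scheme")
  else if (!pop$coverage_ok) E[["BS1.general"]] <- S("not_evaluable")
  else if (is.null(pop$popmax_af)) E[["BS1.general"]] <- S("not_applied")
  else if (pop$popmax_af > th$bs1_af && pop$popmax_af <= th$ba1_af)
    E[["BS1.general"]] <- S("applied", "strong")
  else E[["BS1.general"]] <- S("not_applied")

  if (!enabled("PM2")) E[["PM2.general"]] <- S("disabled_by_scheme")
  else if (!pop$coverage_ok) E[["PM2.general"]] <- S("not_evaluable")
  else if (is.null(pop$popmax_af) || pop$popmax_af < th$pm2_af)
    E[["PM2.general"]] <- S("applied", rd$pm2_strength)
  else E[["PM2.general"]] <- S("not_applied")

  if (!enabled("BS2")) E[["BS2.general"]] <- S("disabled_by_scheme")
  else if (!scheme$bs2_allowed) E[["BS2.general"]] <- S("disabled_by_scheme")
  else if (is.null(pop$flossies_count))
    E[["BS2.general"]] <- S("not_evaluable")
  else if (pop$flossies_count >= th$bs2_count_min)
    E[["BS2.general"]] <- S("applied", rd$bs2_strength)
  else E[["BS2.general"]] <- S("not_applied")

  ## ---- computational, protein ----
  tool_score <- if (scheme$pathogenicity_tool == "revel") sc$revel
                else sc$bayesdel
  strongest_ge <- function(x, cuts) {
    hit <- NA_character_
    if (!is.null(cuts$supporting) && x >= cuts$supporting) hit <- "supporting"
    if (!is.null(cuts$moderate) && x >= cuts$moderate) hit <- "moderate"
    if (!is.null(cuts$strong) && x >= cuts$strong) hit <- "strong"
    if (!is.null(cuts$very_strong) && x >= cuts$very_strong)
      hit <- "very_strong"
    hit
  }
  strongest_le <- function(x, cuts) {
    hit <- NA_character_
    if (!is.null(cuts$supporting) && x <= cuts$supporting) hit <- "supporting"
    if (!is.null(cuts$moderate) && x <= cuts$moderate) hit <- "moderate"
    if (!is.null(cuts$strong) && x <= cuts$strong) hit <- "strong"
    if (!is.null(cuts$very_strong) && x <= cuts$very_strong)
      hit <- "very_strong"
    hit
  }

  if (!enabled("PP3")) {
    E[["PP3.protein"]] <- S("disabled_by_scheme")
  } else if (is.null(tool_score)) {
    E[["PP3.protein"]] <- S("not_evaluable")
  } else {
    s <- strongest_ge(tool_score, th$patho_cuts)
    E[["PP3.protein"]] <- if (!is.na(s)) S("applied", s) else S("not_applied")
  }
  if (!enabled("BP4")) {
    E[["BP4.protein"]] <- S("disabled_by_scheme")
  } else if (is.null(tool_score)) {
    E[["BP4.protein"]] <- S("not_evaluable")
  } else {
    s <- strongest_le(tool_score, th$patho_benign_cuts)
    E[["BP4.protein"]] <- if (!is.na(s)) S("applied", s) else S("not_applied")
  }

  ## ---- computational, splicing ----
  d <- sc$spliceai_max_delta
  if (!enabled("PP3")) E[["PP3.splicing"]] <- S("disabled_by_scheme")
  else if (is.null(d)) E[["PP3.splicing"]] <- S("not_evaluable")
  else if (d >= th$spliceai_pathogenic)
    E[["PP3.splicing"]] <- S("applied", rd$spliceai_pp3_strength)
  else E[["PP3.splicing"]] <- S("not_applied")

  if (!enabled("BP4")) E[["BP4.splicing"]] <- S("disabled_by_scheme")
  else if (is.null(d)) E[["BP4.splicing"]] <- S("not_evaluable")
  else if (d <= th$spliceai_benign)
    E[["BP4.splicing"]] <- S("applied", rd$spliceai_bp4_strength)
  else E[["BP4.splicing"]] <- S("not_applied")

  bp7_scope <- (csq == "synonymous" ||
                (csq == "intronic" && isTRUE(rd$bp7_intronic_allowed))) &&
    !(csq %in% c("splice_donor", "splice_acceptor"))
  if (!enabled("BP7")) E[["BP7.splicing"]] <- S("disabled_by_scheme")
  else if (is.null(d)) E[["BP7.splicing"]] <- S("not_evaluable")
  else if (!bp7_scope) E[["BP7.splicing"]] <- S("not_applied")
  else if (av$rna$status == "confirmed_aberrant")
    E[["BP7.splicing"]] <- S("not_applied")
  else if (d <= th$spliceai_benign)
    E[["BP7.splicing"]] <- S("applied", "supporting")
  else E[["BP7.splicing"]] <- S("not_applied")

  ## ---- PVS1 protein ----
  if (!enabled("PVS1")) {
    E[["PVS1.protein"]] <- S("disabled_by_scheme")
  } else if (csq %in% c("nonsense", "frameshift")) {
    ok_ljo <- !is.null(tx$last_junction_offset) || tx$is_last_exon
    if (!ok_ljo || is.null(tx$protein_length) || is.null(tx$ptc_position)) {
      E[["PVS1.protein"]] <- S("not_evaluable")
    } else if (!tx$is_last_exon && tx$last_junction_offset <= -50) {
      E[["PVS1.protein"]] <- S("applied", "very_strong")
    } else if (pr$domain_overlap) {
      E[["PVS1.protein"]] <- S("applied", "strong")
    } else if ((tx$protein_length - tx$ptc_position) / tx$protein_length
               > 0.10) {
      E[["PVS1.protein"]] <- S("applied", "strong")
    } else {
      E[["PVS1.protein"]] <- S("applied", "moderate")
    }
  } else if (csq == "start_lost") {
    E[["PVS1.protein"]] <- if (isTRUE(rd$start_lost_alternative_start))
      S("applied", "supporting") else S("applied", "moderate")
  } else {
    E[["PVS1.protein"]] <- S("not_applied")
  }

  ## ---- PVS1 splicing ----
  if (!enabled("PVS1")) {
    E[["PVS1.splicing"]] <- S("disabled_by_scheme")
  } else if (!csq %in% c("splice_donor", "splice_acceptor")) {
    E[["PVS1.splicing"]] <- S("not_applied")
  } else if (scheme$rna_integration &&
             av$rna$status == "confirmed_normal_splicing") {
    E[["PVS1.splicing"]] <- S("not_applied")
  } else if (is.null(tx$splice_frame_disrupting)) {
    E[["PVS1.splicing"]] <- S("not_evaluable")
  } else if (tx$splice_frame_disrupting && is.null(tx$splice_nmd)) {
    E[["PVS1.splicing"]] <- S("not_evaluable")
  } else if (tx$splice_frame_disrupting && isTRUE(tx$splice_nmd)) {
    E[["PVS1.splicing"]] <- S("applied", "very_strong")
  } else if (tx$splice_frame_disrupting && pr$domain_overlap) {
    E[["PVS1.splicing"]] <- S("applied", "strong")
  } else if (!tx$splice_frame_disrupting && pr$domain_overlap) {
    E[["PVS1.splicing"]] <- S("applied", "strong")
  } else {
    E[["PVS1.splicing"]] <- S("applied", "moderate")
  }

  ## ---- PS1 / PM5 ----
  spliceogenic <- !is.null(d) && d >= th$spliceai_pathogenic
  if (!enabled("PS1")) E[["PS1.protein"]] <- S("disabled_by_scheme")
  else if (pr$same_aa_change && csq == "missense" && !spliceogenic)
    E[["PS1.protein"]] <- S("applied", "strong")
  else E[["PS1.protein"]] <- S("not_applied")

  if (!enabled("PS1")) E[["PS1.splicing"]] <- S("disabled_by_scheme")
  else if (pr$same_splice_site_pathogenic && is.null(d))
    E[["PS1.splicing"]] <- S("not_evaluable")
  else if (pr$same_splice_site_pathogenic && d >= th$spliceai_pathogenic)
    E[["PS1.splicing"]] <- S("applied", rd$ps1_splicing_strength)
  else E[["PS1.splicing"]] <- S("not_applied")

  if (!enabled("PM5")) E[["PM5.protein"]] <- S("disabled_by_scheme")
  else if (pr$same_codon_other_aa && csq == "missense" && !pr$same_aa_change)
    E[["PM5.protein"]] <- S("applied", "moderate")
  else E[["PM5.protein"]] <- S("not_applied")

  ## ---- structural ----
  if (!enabled("PM1")) E[["PM1.protein"]] <- S("disabled_by_scheme")
  else if (pr$hotspot_overlap) E[["PM1.protein"]] <- S("applied", "moderate")
  else E[["PM1.protein"]] <- S("not_applied")

  if (!enabled("PM4")) E[["PM4.protein"]] <- S("disabled_by_scheme")
  else if ((csq == "inframe_indel" && !pr$repeat_region) ||
           csq == "stop_lost")
    E[["PM4.protein"]] <- S("applied", "moderate")
  else E[["PM4.protein"]] <- S("not_applied")

  if (!enabled("BP3")) E[["BP3.protein"]] <- S("disabled_by_scheme")
  else if (!scheme$bp3_applicable) E[["BP3.protein"]] <- S("disabled_by_scheme")
  else if (csq == "inframe_indel" && pr$repeat_region)
    E[["BP3.protein"]] <- S("applied", "supporting")
  else E[["BP3.protein"]] <- S("not_applied")

  if (!enabled("PP2")) E[["PP2.protein"]] <- S("disabled_by_scheme")
  else if (csq == "missense" && scheme$missense_constrained)
    E[["PP2.protein"]] <- S("applied", "supporting")
  else E[["PP2.protein"]] <- S("not_applied")

  if (!enabled("BP1")) E[["BP1.protein"]] <- S("disabled_by_scheme")
  else if (csq == "missense" && scheme$truncating_mechanism)
    E[["BP1.protein"]] <- S("applied", "supporting")
  else E[["BP1.protein"]] <- S("not_applied")

  ## ---- functional ----
  if (!enabled("PS3")) E[["PS3.general"]] <- S("disabled_by_scheme")
  else if (!scheme$functional_rules_allowed)
    E[["PS3.general"]] <- S("disabled_by_scheme")
  else if (av$assay$status == "absent") E[["PS3.general"]] <- S("not_evaluable")
  else if (av$assay$status == "non_functional")
    E[["PS3.general"]] <- S("applied", av$assay$assay_strength)
  else E[["PS3.general"]] <- S("not_applied")

  if (!enabled("BS3")) E[["BS3.general"]] <- S("disabled_by_scheme")
  else if (!scheme$functional_rules_allowed)
    E[["BS3.general"]] <- S("disabled_by_scheme")
  else if (av$assay$status == "absent") E[["BS3.general"]] <- S("not_evaluable")
  else if (av$assay$status == "functional")
    E[["BS3.general"]] <- S("applied", av$assay$assay_strength)
  else E[["BS3.general"]] <- S("not_applied")

  ## ---- cosegregation ----
  lr <- av$coseg$likelihood_ratio
  meio <- av$coseg$informative_meioses
  contradiction <- !is.null(lr) && !is.null(meio) &&
    lr <= th$bs4_lr_cuts$supporting && meio >= th$pp1_meioses_cuts$supporting
  if (!enabled("PP1")) {
    E[["PP1.general"]] <- S("disabled_by_scheme")
  } else if (is.null(lr) && is.null(meio)) {
    E[["PP1.general"]] <- S("not_evaluable")
  } else if (contradiction) {
    E[["PP1.general"]] <- S("not_evaluable")
  } else if (!is.null(lr)) {
    s <- strongest_ge(lr, th$pp1_lr_cuts)
    E[["PP1.general"]] <- if (!is.na(s)) S("applied", s) else S("not_applied")
  } else {
    s <- strongest_ge(meio, th$pp1_meioses_cuts)
    E[["PP1.general"]] <- if (!is.na(s)) S("applied", s) else S("not_applied")
  }
  if (!enabled("BS4")) {
    E[["BS4.general"]] <- S("disabled_by_scheme")
  } else if (is.null(lr) && is.null(meio)) {
    E[["BS4.general"]] <- S("not_evaluable")
  } else if (contradiction) {
    E[["BS4.general"]] <- S("not_evaluable")
  } else if (!is.null(lr)) {
    s <- strongest_le(lr, th$bs4_lr_cuts)
    E[["BS4.general"]] <- if (!is.na(s)) S("applied", s) else S("not_applied")
  } else {
    E[["BS4.general"]] <- S("not_evaluable")
  }

  ## ---- per-channel classification (independent combiners) ----
  benign_codes <- c("BA1", "BS1", "BS2", "BS3", "BS4", "BP1", "BP3", "BP4",
                    "BP7")
  chan_class <- function(chan) {
    keys <- names(E)
    take <- keys[endsWith(keys, ".general") | endsWith(keys, paste0(".", chan))]
    codes <- sub("\\..*$", "", take)
    rank <- c(supporting = 1, moderate = 2, strong = 3, very_strong = 4,
              stand_alone = 5)
    best <- list()
    for (i in seq_along(take)) {
      e <- E[[take[i]]]
      if (e$status != "applied") next
      code <- codes[i]
      if (is.null(best[[code]]) || rank[[e$strength]] > rank[[best[[code]]]])
        best[[code]] <- e$strength
    }
    pts_map <- scheme$points
    score <- 0
    n <- list(pvs = 0, ps = 0, pm = 0, pp = 0, ba = 0, bs = 0, bm = 0,
              bp = 0)
    for (code in names(best)) {
      s <- best[[code]]
      benign <- code %in% benign_codes
      if (s == "stand_alone") { n$ba <- n$ba + 1; next }
      score <- score + (if (benign) -1 else 1) * pts_map[[s]]
      if (!benign) {
        if (s == "very_strong") n$pvs <- n$pvs + 1
        if (s == "strong") n$ps <- n$ps + 1
        if (s == "moderate") n$pm <- n$pm + 1
        if (s == "supporting") n$pp <- n$pp + 1
      } else {
        if (s %in% c("very_strong", "strong")) n$bs <- n$bs + 1
        if (s == "moderate") n$bm <- n$bm + 1
        if (s == "supporting") n$bp <- n$bp + 1
      }
    }
    b <- scheme$point_class_bounds
    point_cls <- if (n$ba >= 1) "benign"
    else if (score >= b$pathogenic_min) "pathogenic"
    else if (score >= b$likely_pathogenic_min) "likely_pathogenic"
    else if (score >= 0) "vus"
    else if (score > b$benign_max) "likely_benign"
    else "benign"
    acmg <- oracle_acmg_table(n$pvs, n$ps, n$pm, n$pp, n$ba, n$bs,
                              n$bp + n$bm)
    list(acmg_class = acmg, point_score = score, point_class = point_cls)
  }
  protein <- chan_class("protein")
  splicing <- chan_class("splicing")

  final <- oracle_merge_table(protein$point_class, splicing$point_class)
  list(rules = E, protein = protein, splicing = splicing,
       final_class = final)
}

## Independent encoding of the class-combining table on strength counts.
oracle_acmg_table <- function(pvs, ps, pm, pp, ba, bs, bp) {
  if (ba >= 1) return("benign")
  p <- FALSE; lp <- FALSE
  if (pvs >= 1) {
    if (ps >= 1) p <- TRUE
    if (pm >= 2) p <- TRUE
    if (pm == 1 && pp == 1) p <- TRUE
    if (pp >= 2) p <- TRUE
  }
  if (ps >= 2) p <- TRUE
  if (ps == 1) {
    if (pm >= 3) p <- TRUE
    if (pm == 2 && pp >= 2) p <- TRUE
    if (pm == 1 && pp >= 4) p <- TRUE
  }
  if (pvs == 1 && pm == 1) lp <- TRUE
  if (ps == 1 && (pm == 1 || pm == 2)) lp <- TRUE
  if (ps == 1 && pp >= 2) lp <- TRUE
  if (pm >= 3) lp <- TRUE
  if (pm == 2 && pp >= 2) lp <- TRUE
  if (pm == 1 && pp >= 4) lp <- TRUE
  b <- bs >= 2
  lb <- (bs == 1 && bp == 1) || bp >= 2
  if ((p || lp) && (b || lb)) return("vus")
  if (p) return("pathogenic")
  if (lp) return("likely_pathogenic")
  if (b) return("benign")
  if (lb) return("likely_benign")
  "vus"
}

## Independent 25-pair merge table (full enumeration, no shared logic).
oracle_merge_table <- function(a, b) {
  key <- paste(a, b)
  tab <- c(
    "vus vus" = "vus",
    "vus benign" = "benign", "benign vus" = "benign",
    "vus likely_benign" = "likely_benign",
    "likely_benign vus" = "likely_benign",
    "vus likely_pathogenic" = "likely_pathogenic",
    "likely_pathogenic vus" = "likely_pathogenic",
    "vus pathogenic" = "pathogenic", "pathogenic vus" = "pathogenic",
    "benign benign" = "benign",
    "benign likely_benign" = "benign", "likely_benign benign" = "benign",
    "likely_benign likely_benign" = "likely_benign",
    "pathogenic pathogenic" = "pathogenic",
    "pathogenic likely_pathogenic" = "pathogenic",
    "likely_pathogenic pathogenic" = "pathogenic",
    "likely_pathogenic likely_pathogenic" = "likely_pathogenic",
    "benign pathogenic" = "vus", "pathogenic benign" = "vus",
    "benign likely_pathogenic" = "vus", "likely_pathogenic benign" = "vus",
    "likely_benign pathogenic" = "vus", "pathogenic likely_benign" = "vus",
    "likely_benign likely_pathogenic" = "vus",
    "likely_pathogenic likely_benign" = "vus")
  unname(tab[key])
}
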
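#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used across the package.

#' Evidence strengths, weakest to strongest
#' @export
hc_strengths <- function() c("supporting", "moderate", "strong", "very_strong", "stand_alone")

#' Five-tier classification labels, benign to pathogenic
#' @export
hc_classes <- function() {
  c("benign", "likely_benign", "vus", "likely_pathogenic", "pathogenic")
}

hc_channels <- function() c("general", "protein", "splicing")

hc_statuses <- function() c("applied", "not_applied", "not_evaluable", "disabled_by_scheme")

hc_consequences <- function() {
  c("missense", "synonymous", "nonsense", "frameshift", "inframe_indel",
    "splice_donor", "splice_acceptor", "intronic", "start_lost", "stop_lost",
    "UTR")
}

#' Criterion registry
#'
#' The engine automates 19 of the 28 ACMG/AMP criteria: those whose
#' evidence is available in machine-readable form (population frequency,
#' in-silico predictions, prior classifications, functional assays,
#' cosegregation statistics).  Each automated criterion carries a
#' direction (pathogenic or benign), a default evidence strength, and
#' the evidence channels in which it has an implementation: `general`
#' evidence feeds both per-channel classifications, while `protein` and
#' `splicing` implementations feed only their own channel.
#'
#' PP5 and BP6 (reputable-source assertions) are registered but not
#' automatable and are disabled in every scheme, following the
#' recommendation to discontinue them.
#'
#' @return A data frame with one row per registered criterion and
#'   columns `code`, `direction`, `default_strength`, `channels`
#'   (comma-separated), and `automatable`.
#' @export
rule_registry <- function() {
  reg <- data.frame(
    code = c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM4", "PM5", "PP1",
             "PP2", "PP3",
             "BA1", "BS1", "BS2", "BS3", "BS4", "BP1", "BP3", "BP4", "BP7",
             "PP5", "BP6"),
    direction = c(rep("pathogenic", 10), rep("benign", 9),
                  "pathogenic", "benign"),
    default_strength = c("very_strong", "strong", "strong", "moderate",
                         "supporting", "moderate", "moderate", "supporting",
                         "supporting", "supporting",
                         "stand_alone", "strong", "strong", "strong",
                         "strong", "supporting", "supporting", "supporting",
                         "supporting",
                         "supporting", "supporting"),
    channels = c("protein,splicing",   # PVS1
                 "protein,splicing",   # PS1
                 "general",            # PS3
                 "protein",            # PM1
                 "general",            # PM2
                 "protein",            # PM4
                 "protein",            # PM5
                 "general",            # PP1
                 "protein",            # PP2
                 "protein,splicing",   # PP3
                 "general",            # BA1
                 "general",            # BS1
                 "general",            # BS2
                 "general",            # BS3
                 "general",            # BS4
                 "protein",            # BP1
                 "protein",            # BP3
                 "protein,splicing",   # BP4
                 "splicing",           # BP7
                 "general",            # PP5
                 "general"),           # BP6
    automatable = c(rep(TRUE, 19), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  reg
}

#' Codes of the automated criteria, in report order
#'
#' Pathogenic codes first, then benign, each in conventional ACMG order.
#' @export
automated_codes <- function() {
  reg <- rule_registry()
  reg$code[reg$automatable]
}

#' ACMG/AMP criteria outside the automated set
#'
#' The nine criteria the engine does not evaluate, with the evidence
#' category that makes them unavailable to automation: de novo
#' observations (PS2, PM6), allelic data (PM3, BP2, BP5), phenotype
#' specificity (PP4), case-control enrichment (PS4), and
#' reputable-source assertions (PP5, BP6, discontinued by current
#' recommendation and disabled in every scheme).
#'
#' @return Data frame with columns `code` and `category`.
#' @export
excluded_criteria <- function() {
  data.frame(
    code = c("PS2", "PM6", "PM3", "BP2", "BP5", "PP4", "PS4", "PP5", "BP6"),
    category = c("de_novo", "de_novo", "allelic", "allelic", "allelic",
                 "phenotype", "case_control", "reputable_source",
                 "reputable_source"),
    stringsAsFactors = FALSE
  )
}

rule_channels <- function(code) {
  reg <- rule_registry()
  strsplit(reg$channels[match(code, reg$code)], ",")[[1]]
}

rule_direction <- function(code) {
  reg <- rule_registry()
  reg$direction[match(code, reg$code)]
}

## Codes with both a protein and a splicing implementation; these are
## the codes whose cross-channel summarization differs by direction.
dual_channel_codes <- function() c("PVS1", "PS1", "PP3", "BP4")
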
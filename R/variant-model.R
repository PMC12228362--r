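## Domain types. Plain lists with class attributes and eager validation;
## no I/O and no rule logic lives here.

stop_hc <- function(code, msg) {
  stop(structure(class = c(code, "hc_error", "error", "condition"),
                 list(message = sprintf("%s: %s", code, msg), call = NULL)))
}

chk_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_hc("BAD_FIELD", sprintf("'%s' must be TRUE or FALSE", name))
  x
}

chk_enum <- function(x, allowed, name, optional = FALSE) {
  if (is.null(x)) {
    if (optional) return(NULL)
    stop_hc("BAD_FIELD", sprintf("'%s' is required", name))
  }
  if (!is.character(x) || length(x) != 1L || !(x %in% allowed))
    stop_hc("BAD_FIELD", sprintf("'%s' must be one of: %s", name,
                                 paste(allowed, collapse = ", ")))
  x
}

chk_num <- function(x, name, lo = -Inf, hi = Inf, optional = FALSE,
                    integer = FALSE) {
  if (is.null(x)) {
    if (optional) return(NULL)
    stop_hc("BAD_FIELD", sprintf("'%s' is required", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_hc("BAD_FIELD", sprintf("'%s' must be a number in [%s, %s]",
                                 name, lo, hi))
  if (integer && x != round(x))
    stop_hc("BAD_FIELD", sprintf("'%s' must be an integer", name))
  x
}

#' Genomic variant record (GRCh38, 1-based, VCF-style alleles)
#'
#' @param chrom Chromosome label (1-22, X, Y, MT; a "chr" prefix is
#'   tolerated and stripped).
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Non-empty uppercase A/C/G/T allele strings, `ref != alt`.
#' @param gene HGNC gene symbol.
#' @param transcript Identifier of the clinically relevant transcript.
#' @return A `variant_record` object.
#' @export
variant_record <- function(chrom, pos, ref, alt, gene = NA_character_,
                           transcript = NA_character_) {
  chrom <- normalize_chrom(chrom)
  pos <- chk_num(pos, "pos", lo = 1, integer = TRUE)
  for (al in list(c(ref, "ref"), c(alt, "alt"))) {
    if (!is.character(al[1]) || length(al[1]) != 1L || nchar(al[1]) == 0L ||
        grepl("[^ACGT]", al[1]))
      stop_hc("BAD_ALLELE",
              sprintf("'%s' must be a non-empty uppercase A/C/G/T string", al[2]))
  }
  if (ref == alt) stop_hc("BAD_ALLELE", "ref and alt must differ")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, transcript = transcript),
            class = "variant_record")
}

normalize_chrom <- function(chrom) {
  if (!is.character(chrom) || length(chrom) != 1L)
    stop_hc("BAD_CHROM", "chromosome label must be a single string")
  x <- sub("^chr", "", chrom, ignore.case = TRUE)
  if (toupper(x) %in% c("X", "Y")) x <- toupper(x)
  if (toupper(x) %in% c("MT", "M")) x <- "MT"
  if (!x %in% c(as.character(1:22), "X", "Y", "MT"))
    stop_hc("BAD_CHROM", sprintf("unrecognized chromosome label '%s'", chrom))
  x
}

#' Transcript-level annotation of a variant
#'
#' Carries the precomputed transcript facts the criteria consume, so the
#' engine needs no transcript database: the consequence call, the
#' position of a premature termination codon (PTC) relative to the last
#' exon-exon junction (for the 50-nt nonsense-mediated-decay rule), and
#' for canonical splice-site variants the precomputed frame/NMD call for
#' the predicted aberrant transcript.
#'
#' @param consequence One of the supported consequence terms.
#' @param hgvs_c,hgvs_p HGVS annotations (carried through, never parsed).
#' @param exon_index,total_exons 1-based exon index and exon count.
#' @param ptc_position Codon index of a premature termination codon.
#' @param last_junction_offset Signed nt distance of the variant/PTC from
#'   the last exon-exon junction; negative means upstream.  A PTC with
#'   offset <= -50 outside the last exon is NMD-competent.
#' @param protein_length Reference protein length in codons.
#' @param is_last_exon Whether the variant falls in the last exon.
#' @param dist_to_splice_site Signed nt distance to the nearest exon
#'   boundary (for canonical-site variants, +/-1 or +/-2).
#' @param splice_frame_disrupting For canonical splice-site variants:
#'   whether the predicted aberrant event disrupts the reading frame.
#' @param splice_nmd For canonical splice-site variants: whether the
#'   predicted aberrant transcript is expected to undergo NMD.
#' @return A `transcript_annotation` object.
#' @export
transcript_annotation <- function(consequence,
                                  hgvs_c = NA_character_,
                                  hgvs_p = NULL,
                                  exon_index = NULL,
                                  total_exons = NULL,
                                  ptc_position = NULL,
                                  last_junction_offset = NULL,
                                  protein_length = NULL,
                                  is_last_exon = FALSE,
                                  dist_to_splice_site = NULL,
                                  splice_frame_disrupting = NULL,
                                  splice_nmd = NULL) {
  consequence <- chk_enum(consequence, hc_consequences(), "consequence")
  exon_index <- chk_num(exon_index, "exon_index", lo = 1, optional = TRUE,
                        integer = TRUE)
  total_exons <- chk_num(total_exons, "total_exons", lo = 1, optional = TRUE,
                         integer = TRUE)
  if (!is.null(exon_index) && !is.null(total_exons) &&
      exon_index > total_exons)
    stop_hc("BAD_FIELD", "exon_index exceeds total_exons")
  ptc_position <- chk_num(ptc_position, "ptc_position", lo = 1,
                          optional = TRUE, integer = TRUE)
  last_junction_offset <- chk_num(last_junction_offset,
                                  "last_junction_offset", optional = TRUE,
                                  integer = TRUE)
  protein_length <- chk_num(protein_length, "protein_length", lo = 1,
                            optional = TRUE, integer = TRUE)
  is_last_exon <- chk_flag(is_last_exon, "is_last_exon")
  dist_to_splice_site <- chk_num(dist_to_splice_site, "dist_to_splice_site",
                                 optional = TRUE, integer = TRUE)
  if (consequence %in% c("splice_donor", "splice_acceptor")) {
    if (is.null(dist_to_splice_site) ||
        !(abs(dist_to_splice_site) %in% c(1, 2)))
      stop_hc("BAD_FIELD",
              "canonical splice-site consequence requires dist_to_splice_site of +/-1 or +/-2")
  }
  if (!is.null(splice_frame_disrupting))
    splice_frame_disrupting <- chk_flag(splice_frame_disrupting,
                                        "splice_frame_disrupting")
  if (!is.null(splice_nmd)) splice_nmd <- chk_flag(splice_nmd, "splice_nmd")
  structure(list(consequence = consequence, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                 exon_index = exon_index, total_exons = total_exons,
                 ptc_position = ptc_position,
                 last_junction_offset = last_junction_offset,
                 protein_length = protein_length,
                 is_last_exon = is_last_exon,
                 dist_to_splice_site = dist_to_splice_site,
                 splice_frame_disrupting = splice_frame_disrupting,
                 splice_nmd = splice_nmd),
            class = "transcript_annotation")
}

#' Population frequency evidence
#'
#' @param popmax_af Highest continental-population allele frequency
#'   (gnomAD-style popmax), or `NULL` when the variant is absent.
#' @param allele_count Observed allele count (0 when `popmax_af` absent).
#' @param coverage_ok Whether the position is adequately covered in the
#'   reference population resource; frequency criteria are not evaluable
#'   otherwise.
#' @param flossies_count Optional observation count in a cancer-free
#'   aged-women resource (FLOSSIES), consumed by BS2.
#' @export
population_data <- function(popmax_af = NULL, allele_count = 0L,
                            coverage_ok = TRUE, flossies_count = NULL) {
  popmax_af <- chk_num(popmax_af, "popmax_af", lo = 0, hi = 1,
                       optional = TRUE)
  allele_count <- chk_num(allele_count, "allele_count", lo = 0,
                          integer = TRUE)
  coverage_ok <- chk_flag(coverage_ok, "coverage_ok")
  flossies_count <- chk_num(flossies_count, "flossies_count", lo = 0,
                            optional = TRUE, integer = TRUE)
  if (is.null(popmax_af) && allele_count != 0)
    stop_hc("BAD_FIELD", "allele_count must be 0 when popmax_af is absent")
  structure(list(popmax_af = popmax_af,
                 allele_count = as.integer(allele_count),
                 coverage_ok = coverage_ok,
                 flossies_count = flossies_count),
            class = "population_data")
}

#' In-silico prediction scores
#'
#' One pathogenicity predictor (REVEL or BayesDel, selected per scheme)
#' and SpliceAI for splicing, following the single-predictor policy.
#'
#' @param revel REVEL score in \[0,1\].
#' @param bayesdel BayesDel score (unbounded; typical range -1.3..0.6).
#' @param spliceai_max_delta Maximum SpliceAI delta score in \[0,1\].
#' @param spliceai_event Event type of the maximum delta.
#' @export
prediction_scores <- function(revel = NULL, bayesdel = NULL,
                              spliceai_max_delta = NULL,
                              spliceai_event = NULL) {
  revel <- chk_num(revel, "revel", lo = 0, hi = 1, optional = TRUE)
  bayesdel <- chk_num(bayesdel, "bayesdel", optional = TRUE)
  spliceai_max_delta <- chk_num(spliceai_max_delta, "spliceai_max_delta",
                                lo = 0, hi = 1, optional = TRUE)
  spliceai_event <- chk_enum(spliceai_event,
                             c("donor_loss", "donor_gain", "acceptor_loss",
                               "acceptor_gain"),
                             "spliceai_event", optional = TRUE)
  if (!is.null(spliceai_event) && is.null(spliceai_max_delta))
    stop_hc("BAD_FIELD",
            "spliceai_event requires spliceai_max_delta to be present")
  structure(list(revel = revel, bayesdel = bayesdel,
                 spliceai_max_delta = spliceai_max_delta,
                 spliceai_event = spliceai_event),
            class = "prediction_scores")
}

#' Prior-classification and region evidence flags
#'
#' Precomputed boolean evidence from established classifications and
#' region annotations, consumed by PS1, PM5, PM1, PM4, BP3.
#' @param same_aa_change Established pathogenic variant with identical
#'   protein change exists.
#' @param same_codon_other_aa Established pathogenic missense at the
#'   same residue, different substitution.
#' @param same_splice_site_pathogenic Established pathogenic variant at
#'   the same splice site with comparable predicted impact.
#' @param hotspot_overlap Variant lies in a mutational hotspot.
#' @param domain_overlap Variant lies in a functionally critical region.
#' @param repeat_region Variant lies in a repetitive region without
#'   known function.
#' @export
prior_classification <- function(same_aa_change = FALSE,
                                 same_codon_other_aa = FALSE,
                                 same_splice_site_pathogenic = FALSE,
                                 hotspot_overlap = FALSE,
                                 domain_overlap = FALSE,
                                 repeat_region = FALSE) {
  structure(list(
    same_aa_change = chk_flag(same_aa_change, "same_aa_change"),
    same_codon_other_aa = chk_flag(same_codon_other_aa, "same_codon_other_aa"),
    same_splice_site_pathogenic =
      chk_flag(same_splice_site_pathogenic, "same_splice_site_pathogenic"),
    hotspot_overlap = chk_flag(hotspot_overlap, "hotspot_overlap"),
    domain_overlap = chk_flag(domain_overlap, "domain_overlap"),
    repeat_region = chk_flag(repeat_region, "repeat_region")),
    class = "prior_classification")
}

#' Functional assay result (PS3/BS3 input)
#' @param status Assay outcome.
#' @param assay_strength Validated evidence strength of the assay.
#' @export
functional_assay <- function(status = "absent", assay_strength = "strong") {
  status <- chk_enum(status,
                     c("functional", "non_functional", "intermediate",
                       "absent"), "status")
  assay_strength <- chk_enum(assay_strength,
                             c("strong", "moderate", "supporting"),
                             "assay_strength")
  structure(list(status = status, assay_strength = assay_strength),
            class = "functional_assay")
}

#' Cosegregation evidence (PP1/BS4 input)
#' @param likelihood_ratio Bayes cosegregation likelihood ratio (> 0).
#' @param informative_meioses Count of informative meioses.
#' @export
cosegregation_data <- function(likelihood_ratio = NULL,
                               informative_meioses = NULL) {
  likelihood_ratio <- chk_num(likelihood_ratio, "likelihood_ratio",
                              lo = .Machine$double.xmin, optional = TRUE)
  informative_meioses <- chk_num(informative_meioses, "informative_meioses",
                                 lo = 0, optional = TRUE, integer = TRUE)
  structure(list(likelihood_ratio = likelihood_ratio,
                 informative_meioses = informative_meioses),
            class = "cosegregation_data")
}

#' RNA splicing evidence
#' @param status `absent`, `confirmed_aberrant` (RNA data confirms the
#'   predicted aberrant splicing), or `confirmed_normal_splicing`.
#' @export
rna_evidence <- function(status = "absent") {
  status <- chk_enum(status, c("absent", "confirmed_aberrant",
                               "confirmed_normal_splicing"), "status")
  structure(list(status = status), class = "rna_evidence")
}

#' Fully annotated variant: the engine's unit of input
#'
#' @param variant A [variant_record()].
#' @param tx A [transcript_annotation()].
#' @param pop A [population_data()].
#' @param scores A [prediction_scores()].
#' @param prior A [prior_classification()].
#' @param assay A [functional_assay()].
#' @param coseg A [cosegregation_data()].
#' @param rna An [rna_evidence()].
#' @param extra Passthrough bag for fields the engine does not consume.
#' @export
annotated_variant <- function(variant, tx,
                              pop = population_data(),
                              scores = prediction_scores(),
                              prior = prior_classification(),
                              assay = functional_assay(),
                              coseg = cosegregation_data(),
                              rna = rna_evidence(),
                              extra = list()) {
  stopifnot(inherits(variant, "variant_record"),
            inherits(tx, "transcript_annotation"),
            inherits(pop, "population_data"),
            inherits(scores, "prediction_scores"),
            inherits(prior, "prior_classification"),
            inherits(assay, "functional_assay"),
            inherits(coseg, "cosegregation_data"),
            inherits(rna, "rna_evidence"))
  structure(list(variant = variant, tx = tx, pop = pop, scores = scores,
                 prior = prior, assay = assay, coseg = coseg, rna = rna,
                 extra = extra),
            class = "annotated_variant")
}

#' Outcome of one criterion in one evidence channel
#'
#' @param code Criterion code (e.g. `PVS1`).
#' @param channel `general`, `protein` or `splicing`.
#' @param status `applied`, `not_applied`, `not_evaluable` or
#'   `disabled_by_scheme`.
#' @param strength Evidence strength; required when `status = "applied"`.
#' @param comment Explanation; required unless `status = "not_evaluable"`
#'   (where it lists missing inputs when known).
#' @export
rule_result <- function(code, channel, status, strength = NULL,
                        comment = "") {
  channel <- chk_enum(channel, hc_channels(), "channel")
  status <- chk_enum(status, hc_statuses(), "status")
  if (status == "applied") {
    strength <- chk_enum(strength, hc_strengths(), "strength")
    if (!nzchar(comment))
      stop_hc("BAD_FIELD", "applied rule_result requires a comment")
  }
  if (status != "not_evaluable" && !nzchar(comment))
    stop_hc("BAD_FIELD", "rule_result requires a comment")
  structure(list(code = code, channel = channel, status = status,
                 strength = strength, comment = comment),
            class = "rule_result")
}

#' Point value of an evidence strength
#'
#' Additive scoring: supporting = 1, moderate = 2, strong = 4,
#' very strong = 8 points, negated for benign-direction criteria.
#' Stand-alone evidence (BA1) has no point value; it short-circuits in
#' the combiner.  The constants are read from configuration so
#' alternative calibrations can be swapped in.
#'
#' @param strength An evidence strength other than `stand_alone`.
#' @param direction `"pathogenic"` or `"benign"`.
#' @param points Named strength-to-points map (defaults to the shipped
#'   configuration).
#' @return Signed integer point value.
#' @export
point_value <- function(strength, direction = c("pathogenic", "benign"),
                        points = default_points()) {
  direction <- match.arg(direction)
  if (identical(strength, "stand_alone"))
    stop_hc("STAND_ALONE",
            "stand-alone has no point value; handled by combiner short-circuit")
  strength <- chk_enum(strength, setdiff(hc_strengths(), "stand_alone"),
                       "strength")
  v <- points[[strength]]
  if (direction == "benign") -v else v
}

default_points <- function() {
  hc_defaults()$points
}
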
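## Scheme configuration: base ACMG and the seven gene-specific schemes,
## loaded from YAML and validated eagerly.

#' Directory holding the shipped scheme configuration
#' @export
default_config_dir <- function() {
  system.file("config", package = "hbocclassify")
}

scheme_ids <- function() {
  c("acmg_base", "atm", "brca1", "brca2", "cdh1", "palb2", "pten", "tp53")
}

required_scheme_keys <- function() {
  c("scheme_id", "version_label", "gene", "pathogenicity_tool",
    "splicing_tool", "bs2_allowed", "functional_rules_allowed",
    "bp3_applicable", "missense_constrained", "truncating_mechanism",
    "rna_integration", "enabled_rules")
}

required_threshold_keys <- function() {
  c("ba1_af", "bs1_af", "pm2_af", "spliceai_pathogenic", "spliceai_benign",
    "bs2_count_min", "patho_tool_cuts", "patho_tool_benign_cuts",
    "pp1_lr_cuts", "bs4_lr_cuts", "pp1_meioses_cuts")
}

hc_defaults <- local({
  cache <- NULL
  function(config_dir = default_config_dir()) {
    if (!is.null(cache) && identical(attr(cache, "dir"), config_dir))
      return(cache)
    path <- file.path(config_dir, "defaults.yaml")
    if (!file.exists(path))
      stop_hc("CONFIG_INCOMPLETE", sprintf("defaults file not found: %s", path))
    d <- yaml::read_yaml(path)
    for (k in c("points", "point_class_bounds", "thresholds", "rule_defaults"))
      if (is.null(d[[k]]))
        stop_hc("CONFIG_INCOMPLETE", sprintf("defaults.yaml misses '%s'", k))
    attr(d, "dir") <- config_dir
    cache <<- d
    d
  }
})

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else
      base[[k]] <- override[[k]]
  }
  base
}

#' Load and validate one classification scheme
#'
#' Reads the shared defaults and the scheme file, applies optional
#' overrides, resolves the predictor-specific cut tables for the
#' scheme's pathogenicity tool, and checks every structural invariant:
#' frequency-cut ordering (`ba1_af > bs1_af > pm2_af`), SpliceAI cut
#' ordering, monotonicity of all strength-cut maps, the gene-specific
#' gates on BS2 / PS3-BS3 / BP3, and the predictor assignment
#' (BayesDel for BRCA1, BRCA2, TP53; REVEL otherwise).
#'
#' @param scheme_id One of `acmg_base`, `atm`, `brca1`, `brca2`,
#'   `cdh1`, `palb2`, `pten`, `tp53`.
#' @param config_dir Directory with `defaults.yaml` and one YAML file
#'   per scheme.
#' @param overrides_file Optional YAML file whose keys override the
#'   merged configuration (e.g. an alternative threshold profile).
#' @return A validated `scheme_config` object.
#' @export
load_scheme <- function(scheme_id, config_dir = default_config_dir(),
                        overrides_file = NULL) {
  if (!scheme_id %in% scheme_ids())
    stop_hc("CONFIG_INVALID", sprintf("unknown scheme_id '%s'", scheme_id))
  path <- file.path(config_dir, paste0(scheme_id, ".yaml"))
  if (!file.exists(path))
    stop_hc("CONFIG_INCOMPLETE", sprintf("scheme file not found: %s", path))
  raw <- yaml::read_yaml(path)

  unknown <- setdiff(names(raw), c(required_scheme_keys(),
                                   "thresholds", "rule_defaults"))
  if (length(unknown))
    stop_hc("CONFIG_INVALID",
            sprintf("unknown keys in %s: %s", basename(path),
                    paste(unknown, collapse = ", ")))
  missing <- setdiff(setdiff(required_scheme_keys(), "gene"), names(raw))
  if (length(missing))
    stop_hc("CONFIG_INCOMPLETE",
            sprintf("%s misses keys: %s", basename(path),
                    paste(missing, collapse = ", ")))

  d <- hc_defaults(config_dir)
  cfg <- list(points = d$points,
              point_class_bounds = d$point_class_bounds,
              thresholds = d$thresholds,
              rule_defaults = d$rule_defaults)
  cfg$thresholds <- merge_config(cfg$thresholds, raw$thresholds %||% list())
  cfg$rule_defaults <- merge_config(cfg$rule_defaults,
                                    raw$rule_defaults %||% list())
  if (!is.null(overrides_file)) {
    ov <- yaml::read_yaml(overrides_file)
    cfg <- merge_config(cfg, ov)
  }

  th <- cfg$thresholds
  missing_th <- setdiff(required_threshold_keys(), names(th))
  if (length(missing_th))
    stop_hc("CONFIG_INCOMPLETE",
            sprintf("missing thresholds: %s", paste(missing_th, collapse = ", ")))

  tool <- raw$pathogenicity_tool
  if (!tool %in% c("revel", "bayesdel"))
    stop_hc("CONFIG_INVALID", "pathogenicity_tool must be revel or bayesdel")
  th$patho_cuts <- th$patho_tool_cuts[[tool]]
  th$patho_benign_cuts <- th$patho_tool_benign_cuts[[tool]]
  if (is.null(th$patho_cuts) || is.null(th$patho_benign_cuts))
    stop_hc("CONFIG_INCOMPLETE",
            sprintf("no strength cuts configured for tool '%s'", tool))

  scheme <- structure(list(
    scheme_id = raw$scheme_id,
    version_label = raw$version_label,
    gene = raw$gene,
    enabled_rules = unlist(raw$enabled_rules),
    thresholds = th,
    pathogenicity_tool = tool,
    splicing_tool = raw$splicing_tool,
    bs2_allowed = isTRUE(raw$bs2_allowed),
    functional_rules_allowed = isTRUE(raw$functional_rules_allowed),
    bp3_applicable = isTRUE(raw$bp3_applicable),
    missense_constrained = isTRUE(raw$missense_constrained),
    truncating_mechanism = isTRUE(raw$truncating_mechanism),
    rna_integration = isTRUE(raw$rna_integration),
    rule_defaults = cfg$rule_defaults,
    points = cfg$points,
    point_class_bounds = cfg$point_class_bounds
  ), class = "scheme_config")
  validate_scheme(scheme)
  scheme
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_scheme <- function(s) {
  if (!identical(s$scheme_id, make.names(s$scheme_id)) ||
      !s$scheme_id %in% scheme_ids())
    stop_hc("CONFIG_INVALID", sprintf("bad scheme_id '%s'", s$scheme_id))
  if (s$splicing_tool != "spliceai")
    stop_hc("CONFIG_INVALID", "splicing_tool is fixed to spliceai")
  bad <- setdiff(s$enabled_rules, automated_codes())
  if (length(bad))
    stop_hc("CONFIG_INVALID",
            sprintf("enabled_rules contains non-automatable codes: %s",
                    paste(bad, collapse = ", ")))
  th <- s$thresholds
  if (!(th$ba1_af > th$bs1_af && th$bs1_af > th$pm2_af))
    stop_hc("CONFIG_INVALID", "require ba1_af > bs1_af > pm2_af")
  if (!(th$spliceai_pathogenic > th$spliceai_benign))
    stop_hc("CONFIG_INVALID",
            "require spliceai_pathogenic > spliceai_benign")
  chk_mono <- function(cuts, increasing, what) {
    ord <- intersect(c("supporting", "moderate", "strong", "very_strong"),
                     names(cuts))
    v <- unlist(cuts[ord])
    if (length(v) > 1 && any(if (increasing) diff(v) <= 0 else diff(v) >= 0))
      stop_hc("CONFIG_INVALID",
              sprintf("%s cuts must be monotone in strength", what))
  }
  chk_mono(th$patho_cuts, TRUE, "pathogenic predictor")
  chk_mono(th$patho_benign_cuts, FALSE, "benign predictor")
  chk_mono(th$pp1_lr_cuts, TRUE, "PP1 LR")
  chk_mono(th$bs4_lr_cuts, FALSE, "BS4 LR")
  chk_mono(th$pp1_meioses_cuts, TRUE, "PP1 meioses")
  # Gene-specific gates documented in the scheme registry.
  if (s$scheme_id %in% c("brca1", "brca2", "palb2", "pten") && s$bs2_allowed)
    stop_hc("CONFIG_INVALID",
            sprintf("BS2 is not available under the %s scheme", s$scheme_id))
  if (s$functional_rules_allowed && !s$scheme_id %in% c("brca1", "brca2"))
    stop_hc("CONFIG_INVALID",
            "functional-assay criteria are automated only for BRCA1/BRCA2")
  if (s$bp3_applicable && s$scheme_id != "acmg_base")
    stop_hc("CONFIG_INVALID",
            "BP3 is not applicable under any gene-specific scheme")
  expected_tool <- if (s$scheme_id %in% c("brca1", "brca2", "tp53"))
    "bayesdel" else "revel"
  if (s$pathogenicity_tool != expected_tool)
    stop_hc("CONFIG_INVALID",
            sprintf("scheme %s must use %s", s$scheme_id, expected_tool))
  invisible(s)
}

#' Load every shipped scheme
#'
#' @inheritParams load_scheme
#' @return Named list of `scheme_config` objects keyed by scheme id.
#' @export
scheme_registry <- function(config_dir = default_config_dir(),
                            overrides_file = NULL) {
  reg <- lapply(scheme_ids(), load_scheme, config_dir = config_dir,
                overrides_file = overrides_file)
  names(reg) <- scheme_ids()
  reg
}

#' Select the scheme for a gene
#'
#' Returns the gene-specific scheme when one exists, the base ACMG
#' scheme otherwise.  Gene symbols match case-insensitively.
#'
#' @param gene HGNC gene symbol (or `NA`).
#' @param registry A [scheme_registry()].
#' @export
select_scheme <- function(gene, registry = scheme_registry()) {
  if (is.null(registry$acmg_base))
    stop_hc("CONFIG_INCOMPLETE", "registry must contain acmg_base")
  if (is.null(gene) || is.na(gene)) return(registry$acmg_base)
  genes <- vapply(registry, function(s) s$gene %||% NA_character_,
                  character(1))
  hit <- which(toupper(genes) == toupper(gene))
  if (length(hit)) registry[[hit[1]]] else registry$acmg_base
}

#' Restrict a scheme to a user-selected rule subset
#'
#' The engine evaluates only the intersection of the scheme's enabled
#' rules with `user_selection`; every other registered criterion
#' reports `disabled_by_scheme`.
#'
#' @param scheme A `scheme_config`.
#' @param user_selection Character vector of criterion codes; must be a
#'   subset of the automated codes.
#' @export
restrict_rules <- function(scheme, user_selection) {
  unknown <- setdiff(user_selection, automated_codes())
  if (length(unknown))
    stop_hc("UNKNOWN_RULE",
            sprintf("not in the automated criterion registry: %s",
                    paste(unknown, collapse = ", ")))
  scheme$enabled_rules <- intersect(scheme$enabled_rules, user_selection)
  scheme
}
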
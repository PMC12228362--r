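## Deterministic synthetic-fixture generator. Produces annotated
## variants that exercise every criterion, scheme and combiner, with
## expectation sidecars computed by the independent straight-line
## oracle (oracle.R), never by the engine.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort generation parameters
#'
#' The grids straddle every configured threshold and include the exact
#' cut values, so boundary semantics (strict vs inclusive comparisons)
#' are pinned by the generated fixtures.
#'
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param n Number of variants.
#' @param genes Gene symbols to draw from (scheme genes plus genes
#'   without a gene-specific scheme).
#' @param af_grid Popmax allele-frequency grid.
#' @param revel_grid,bayesdel_grid,spliceai_grid Predictor score grids.
#' @export
fixture_spec <- function(seed = 1L, n = 100L,
                         genes = c("ATM", "BRCA1", "BRCA2", "CDH1",
                                   "PALB2", "PTEN", "TP53",
                                   "CHEK2", "MSH2", "RAD51D", "PMS2",
                                   "BRIP1"),
                         af_grid = c(0, 5e-6, 1e-5, 2e-5, 5e-5, 1e-4,
                                     2e-4, 5e-4, 1e-3, 2e-3, 0.02),
                         revel_grid = c(0.01, 0.016, 0.1, 0.183, 0.29,
                                        0.5, 0.644, 0.7, 0.773, 0.9,
                                        0.932, 0.95),
                         bayesdel_grid = c(-0.5, -0.36, -0.2, -0.18, 0,
                                           0.13, 0.2, 0.27, 0.4, 0.5,
                                           0.55),
                         spliceai_grid = c(0, 0.05, 0.1, 0.15, 0.2,
                                           0.5, 0.9)) {
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 genes = genes, af_grid = af_grid,
                 revel_grid = revel_grid, bayesdel_grid = bayesdel_grid,
                 spliceai_grid = spliceai_grid),
            class = "fixture_spec")
}

maybe <- function(p, value) if (stats::runif(1) < p) value else NULL

random_annotated_variant <- function(spec) {
  gene <- sample(spec$genes, 1)
  csq <- sample(hc_consequences(), 1)
  pos <- sample.int(2e8, 1)
  base_pair <- sample(c("A", "C", "G", "T"), 2, replace = FALSE)
  v <- variant_record(sample(c(as.character(1:22), "X"), 1), pos,
                      base_pair[1], base_pair[2], gene = gene,
                      transcript = paste0("NM_", sample.int(99999, 1)))

  total_exons <- sample(5:25, 1)
  is_last <- stats::runif(1) < 0.2
  exon_index <- if (is_last) total_exons else sample.int(total_exons - 1, 1)
  tx_args <- list(consequence = csq,
                  hgvs_c = sprintf("c.%d%s>%s", pos %% 5000 + 1,
                                   base_pair[1], base_pair[2]),
                  exon_index = exon_index, total_exons = total_exons,
                  is_last_exon = is_last)
  if (csq %in% c("nonsense", "frameshift")) {
    pl <- sample(200:2000, 1)
    tx_args$protein_length <- maybe(0.95, pl)
    tx_args$ptc_position <- maybe(0.95, sample.int(pl, 1))
    tx_args$last_junction_offset <-
      maybe(0.9, sample(c(-300L, -120L, -51L, -50L, -49L, -10L, 20L), 1))
  }
  if (csq %in% c("splice_donor", "splice_acceptor")) {
    tx_args$dist_to_splice_site <- sample(c(-2L, -1L, 1L, 2L), 1)
    fd <- maybe(0.9, stats::runif(1) < 0.6)
    tx_args$splice_frame_disrupting <- fd
    if (isTRUE(fd)) tx_args$splice_nmd <- maybe(0.9, stats::runif(1) < 0.6)
  }
  if (csq == "intronic")
    tx_args$dist_to_splice_site <- sample(c(-200L, -30L, 8L, 40L), 1)
  tx <- do.call(transcript_annotation, tx_args)

  af <- maybe(0.7, sample(spec$af_grid, 1))
  pop <- population_data(
    popmax_af = af,
    allele_count = if (is.null(af)) 0L else sample.int(500, 1),
    coverage_ok = stats::runif(1) < 0.9,
    flossies_count = maybe(0.4, sample(c(0L, 5L, 9L, 10L, 11L, 20L), 1)))

  protein_scored <- csq %in% c("missense", "inframe_indel", "stop_lost")
  scores <- prediction_scores(
    revel = if (protein_scored) maybe(0.8, sample(spec$revel_grid, 1)),
    bayesdel = if (protein_scored)
      maybe(0.8, sample(spec$bayesdel_grid, 1)),
    spliceai_max_delta = maybe(0.85, sample(spec$spliceai_grid, 1)))

  prior <- prior_classification(
    same_aa_change = csq == "missense" && stats::runif(1) < 0.1,
    same_codon_other_aa = csq == "missense" && stats::runif(1) < 0.1,
    same_splice_site_pathogenic = stats::runif(1) < 0.08,
    hotspot_overlap = stats::runif(1) < 0.08,
    domain_overlap = stats::runif(1) < 0.25,
    repeat_region = stats::runif(1) < 0.15)

  assay <- if (stats::runif(1) < 0.25)
    functional_assay(sample(c("functional", "non_functional",
                              "intermediate"), 1),
                     sample(c("strong", "moderate", "supporting"), 1))
  else functional_assay()

  coseg_mode <- sample(c("none", "lr", "meioses", "both"), 1,
                       prob = c(0.55, 0.25, 0.12, 0.08))
  lr_grid <- c(0.01, 0.053, 0.1, 0.23, 0.48, 1, 2.08, 4.33, 10, 18.7, 400)
  coseg <- switch(coseg_mode,
    none = cosegregation_data(),
    lr = cosegregation_data(likelihood_ratio = sample(lr_grid, 1)),
    meioses = cosegregation_data(informative_meioses =
                                   sample(c(1L, 3L, 5L, 7L, 12L), 1)),
    both = cosegregation_data(likelihood_ratio = sample(lr_grid, 1),
                              informative_meioses =
                                sample(c(1L, 3L, 5L, 7L, 12L), 1)))

  rna <- if (gene %in% c("BRCA1", "BRCA2") && stats::runif(1) < 0.3)
    rna_evidence(sample(c("confirmed_aberrant",
                          "confirmed_normal_splicing"), 1))
  else rna_evidence()

  annotated_variant(v, tx, pop, scores, prior, assay, coseg, rna)
}

#' Generate a triggering / non-triggering fixture pair for one criterion
#'
#' The triggering record makes the criterion fire in the requested
#' channel under the scheme; the matched record differs in the minimal
#' evidence field and does not fire it.  Combinations the scheme rules
#' out (BS2 under BRCA1/BRCA2/PALB2/PTEN, PS3/BS3 outside BRCA1/BRCA2,
#' BP3 under any gene-specific scheme) are refused with an error naming
#' the scheme gate.
#'
#' @param code Criterion code.
#' @param channel Evidence channel the criterion should fire in.
#' @param scheme_id Scheme identifier.
#' @param seed Integer seed.
#' @param config_dir Configuration directory.
#' @return List with `trigger` and `control` annotated variants.
#' @export
generate_rule_fixture <- function(code, channel = NULL,
                                  scheme_id = "acmg_base", seed = 1L,
                                  config_dir = default_config_dir()) {
  scheme <- load_scheme(scheme_id, config_dir)
  if (!code %in% automated_codes())
    stop_hc("UNKNOWN_RULE", sprintf("'%s' is not an automated criterion", code))
  channel <- channel %||% rule_channels(code)[1]
  if (!channel %in% rule_channels(code))
    stop_hc("BAD_FIELD",
            sprintf("%s has no %s implementation", code, channel))
  if (code == "BS2" && !scheme$bs2_allowed)
    stop_hc("IMPOSSIBLE_FIXTURE",
            sprintf("BS2 is not available under the %s scheme (healthy-observation resource not admitted)",
                    scheme_id))
  if (code %in% c("PS3", "BS3") && !scheme$functional_rules_allowed)
    stop_hc("IMPOSSIBLE_FIXTURE",
            sprintf("functional-assay criteria are not automated under the %s scheme",
                    scheme_id))
  if (code == "BP3" && !scheme$bp3_applicable)
    stop_hc("IMPOSSIBLE_FIXTURE",
            sprintf("BP3 is not applicable under the %s scheme", scheme_id))
  if (code %in% c("PP2", "BP1")) {
    flag <- if (code == "PP2") scheme$missense_constrained
            else scheme$truncating_mechanism
    if (!flag)
      stop_hc("IMPOSSIBLE_FIXTURE",
              sprintf("%s requires the %s gene-mechanism flag of the scheme",
                      code,
                      if (code == "PP2") "missense-constrained"
                      else "truncating-mechanism"))
  }

  th <- scheme$thresholds
  gene <- scheme$gene %||% "CHEK2"
  with_seed(seed, {
    base <- function(csq = "missense", ...) {
      annotated_variant(
        variant_record("17", sample.int(1e8, 1), "G", "A", gene = gene),
        transcript_annotation(consequence = csq, exon_index = 3,
                              total_exons = 12, ...),
        population_data(popmax_af = NULL, allele_count = 0L,
                        coverage_ok = TRUE))
    }
    tweak <- function(av, ...) {
      mods <- list(...)
      for (k in names(mods)) av[[k]] <- mods[[k]]
      av
    }
    eps <- 1e-9
    pair <- switch(code,
      BA1 = {
        t <- base(); c <- base()
        t$pop <- population_data(th$ba1_af * 2, 100L, TRUE)
        c$pop <- population_data(th$ba1_af / 2, 100L, TRUE)
        list(t, c)
      },
      BS1 = {
        t <- base(); c <- base()
        t$pop <- population_data(th$bs1_af * 2, 50L, TRUE)
        c$pop <- population_data(th$bs1_af / 2, 10L, TRUE)
        list(t, c)
      },
      PM2 = {
        t <- base(); c <- base()
        c$pop <- population_data(th$pm2_af, 5L, TRUE)
        list(t, c)
      },
      BS2 = {
        t <- base(); c <- base()
        t$pop <- population_data(NULL, 0L, TRUE,
                                 flossies_count = th$bs2_count_min)
        c$pop <- population_data(NULL, 0L, TRUE,
                                 flossies_count = th$bs2_count_min - 1L)
        list(t, c)
      },
      PP3 = if (channel == "protein") {
        t <- base(); c <- base()
        cut <- th$patho_cuts$supporting
        t$scores <- if (scheme$pathogenicity_tool == "revel")
          prediction_scores(revel = cut) else prediction_scores(bayesdel = cut)
        c$scores <- if (scheme$pathogenicity_tool == "revel")
          prediction_scores(revel = cut - 0.05)
        else prediction_scores(bayesdel = cut - 0.05)
        list(t, c)
      } else {
        t <- base("intronic", dist_to_splice_site = 30)
        c <- base("intronic", dist_to_splice_site = 30)
        t$scores <- prediction_scores(spliceai_max_delta =
                                        th$spliceai_pathogenic)
        c$scores <- prediction_scores(spliceai_max_delta =
                                        th$spliceai_pathogenic - 0.05)
        list(t, c)
      },
      BP4 = if (channel == "protein") {
        t <- base(); c <- base()
        cut <- th$patho_benign_cuts$supporting
        t$scores <- if (scheme$pathogenicity_tool == "revel")
          prediction_scores(revel = cut) else prediction_scores(bayesdel = cut)
        c$scores <- if (scheme$pathogenicity_tool == "revel")
          prediction_scores(revel = cut + 0.05)
        else prediction_scores(bayesdel = cut + 0.05)
        list(t, c)
      } else {
        t <- base(); c <- base()
        t$scores <- prediction_scores(spliceai_max_delta = th$spliceai_benign)
        c$scores <- prediction_scores(spliceai_max_delta =
                                        th$spliceai_benign + 0.05)
        list(t, c)
      },
      BP7 = {
        t <- base("synonymous"); c <- base("synonymous")
        t$scores <- prediction_scores(spliceai_max_delta = th$spliceai_benign)
        c$scores <- prediction_scores(spliceai_max_delta =
                                        th$spliceai_benign + 0.05)
        list(t, c)
      },
      PVS1 = if (channel == "protein") {
        t <- base("nonsense", protein_length = 800, ptc_position = 300,
                  last_junction_offset = -120)
        c <- base("missense")
        list(t, c)
      } else {
        t <- base("splice_donor", dist_to_splice_site = 1,
                  splice_frame_disrupting = TRUE, splice_nmd = TRUE)
        c <- base("missense")
        list(t, c)
      },
      PS1 = if (channel == "protein") {
        t <- base(); c <- base()
        t$prior <- prior_classification(same_aa_change = TRUE)
        list(t, c)
      } else {
        t <- base("intronic", dist_to_splice_site = -5)
        c <- base("intronic", dist_to_splice_site = -5)
        t$prior <- prior_classification(same_splice_site_pathogenic = TRUE)
        t$scores <- prediction_scores(spliceai_max_delta = 0.9)
        c$scores <- prediction_scores(spliceai_max_delta = 0.9)
        list(t, c)
      },
      PM5 = {
        t <- base(); c <- base()
        t$prior <- prior_classification(same_codon_other_aa = TRUE)
        list(t, c)
      },
      PM1 = {
        t <- base(); c <- base()
        t$prior <- prior_classification(hotspot_overlap = TRUE)
        list(t, c)
      },
      PM4 = {
        t <- base("inframe_indel"); c <- base("inframe_indel")
        c$prior <- prior_classification(repeat_region = TRUE)
        list(t, c)
      },
      BP3 = {
        t <- base("inframe_indel"); c <- base("inframe_indel")
        t$prior <- prior_classification(repeat_region = TRUE)
        list(t, c)
      },
      PP2 = {
        t <- base(); c <- base("synonymous")
        list(t, c)
      },
      BP1 = {
        t <- base(); c <- base("synonymous")
        list(t, c)
      },
      PS3 = {
        t <- base(); c <- base()
        t$assay <- functional_assay("non_functional", "strong")
        c$assay <- functional_assay("intermediate", "strong")
        list(t, c)
      },
      BS3 = {
        t <- base(); c <- base()
        t$assay <- functional_assay("functional", "strong")
        c$assay <- functional_assay("intermediate", "strong")
        list(t, c)
      },
      PP1 = {
        t <- base(); c <- base()
        t$coseg <- cosegregation_data(likelihood_ratio =
                                        th$pp1_lr_cuts$supporting)
        c$coseg <- cosegregation_data(likelihood_ratio =
                                        th$pp1_lr_cuts$supporting - eps)
        list(t, c)
      },
      BS4 = {
        t <- base(); c <- base()
        t$coseg <- cosegregation_data(likelihood_ratio =
                                        th$bs4_lr_cuts$supporting)
        c$coseg <- cosegregation_data(likelihood_ratio =
                                        th$bs4_lr_cuts$supporting + eps)
        list(t, c)
      },
      stop_hc("UNKNOWN_RULE", sprintf("no fixture recipe for %s", code)))
    list(trigger = pair[[1]], control = pair[[2]])
  })
}

#' Generate a seeded synthetic cohort with an expectations sidecar
#'
#' Writes the cohort as JSON Lines and, next to it, an expectations
#' sidecar (`<path>.expected.jsonl`) holding the per-variant rule
#' statuses, channel classes, point scores and final class computed by
#' the independent straight-line oracle ([oracle_expectations()]),
#' never by the engine.  Identical seeds give byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param path Output path for the cohort JSON Lines file.
#' @param config_dir Configuration directory for scheme selection.
#' @return List with `cohort` and `expectations` paths and the
#'   in-memory `variants` and `expected` lists.
#' @export
generate_cohort <- function(spec, path,
                            config_dir = default_config_dir()) {
  stopifnot(inherits(spec, "fixture_spec"))
  registry <- scheme_registry(config_dir)
  variants <- with_seed(spec$seed,
                        lapply(seq_len(spec$n),
                               function(i) random_annotated_variant(spec)))
  expected <- lapply(variants, function(av) {
    scheme <- select_scheme(av$variant$gene, registry)
    e <- oracle_expectations(av, scheme)
    e$scheme_id <- scheme$scheme_id
    e
  })
  write_annotated_json(variants, path)
  exp_path <- paste0(path, ".expected.jsonl")
  lines <- vapply(expected, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1))
  writeLines(lines, exp_path)
  list(cohort = path, expectations = exp_path, variants = variants,
       expected = expected)
}

#' Replay a cohort through the engine and compare with its expectations
#'
#' @param variants List of [annotated_variant()].
#' @param expected Parallel list of oracle expectations.
#' @param registry A [scheme_registry()].
#' @return List with `n`, `n_concordant`, `concordance` (fraction), and
#'   a data frame `mismatches`.
#' @export
replay_cohort <- function(variants, expected,
                          registry = scheme_registry()) {
  mism <- list()
  n_ok <- 0L
  for (i in seq_along(variants)) {
    av <- variants[[i]]
    e <- expected[[i]]
    scheme <- select_scheme(av$variant$gene, registry)
    rep <- classify_variant(av, scheme)
    ok <- TRUE
    for (r in rep$all_results) {
      key <- paste(r$code, r$channel, sep = ".")
      exp_r <- e$rules[[key]]
      if (is.null(exp_r) || r$status != exp_r$status ||
          (r$status == "applied" &&
           !identical(r$strength, exp_r$strength))) {
        ok <- FALSE
        mism[[length(mism) + 1L]] <-
          data.frame(i = i, what = key,
                     engine = paste(r$status, r$strength %||% ""),
                     oracle = paste(exp_r$status %||% "<none>",
                                    exp_r$strength %||% ""))
      }
    }
    for (ch in c("protein", "splicing")) {
      for (f in c("acmg_class", "point_class")) {
        if (!identical(rep[[ch]][[f]], e[[ch]][[f]])) {
          ok <- FALSE
          mism[[length(mism) + 1L]] <-
            data.frame(i = i, what = paste(ch, f),
                       engine = rep[[ch]][[f]], oracle = e[[ch]][[f]])
        }
      }
      if (rep[[ch]]$point_score != e[[ch]]$point_score) {
        ok <- FALSE
        mism[[length(mism) + 1L]] <-
          data.frame(i = i, what = paste(ch, "point_score"),
                     engine = as.character(rep[[ch]]$point_score),
                     oracle = as.character(e[[ch]]$point_score))
      }
    }
    if (!identical(rep$final_class, e$final_class)) {
      ok <- FALSE
      mism[[length(mism) + 1L]] <-
        data.frame(i = i, what = "final_class", engine = rep$final_class,
                   oracle = e$final_class)
    }
    if (ok) n_ok <- n_ok + 1L
  }
  list(n = length(variants), n_concordant = n_ok,
       concordance = if (length(variants)) n_ok / length(variants) else 1,
       mismatches = if (length(mism)) do.call(rbind, mism)
                    else data.frame())
}
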
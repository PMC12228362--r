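th_base <- hc_base$thresholds

test_that("population criteria partition the allele-frequency axis", {
  # common variant: BA1 stand-alone, nothing else on the benign axis
  res <- run_rules(av_fix(pop = population_data(0.02, 100L, TRUE)), hc_base)
  expect_identical(rule_status(res, "BA1", "general"), "applied")
  expect_identical(get_result(res, "BA1", "general")$strength,
                   "stand_alone")
  expect_identical(rule_status(res, "BS1", "general"), "not_applied")
  expect_identical(rule_status(res, "PM2", "general"), "not_applied")

  # BS1 band: between bs1_af and ba1_af
  res <- run_rules(av_fix(pop = population_data(th_base$bs1_af * 2, 50L,
                                                TRUE)), hc_base)
  expect_identical(rule_status(res, "BA1", "general"), "not_applied")
  expect_identical(rule_status(res, "BS1", "general"), "applied")

  # absent variant at adequate coverage: PM2 at supporting (downgraded)
  res <- run_rules(av_fix(pop = population_data(NULL, 0L, TRUE)), hc_base)
  pm2 <- get_result(res, "PM2", "general")
  expect_identical(pm2$status, "applied")
  expect_identical(pm2$strength, "supporting")

  # inadequate coverage: frequency criteria not evaluable
  res <- run_rules(av_fix(pop = population_data(NULL, 0L, FALSE)), hc_base)
  for (code in c("BA1", "BS1", "PM2"))
    expect_identical(rule_status(res, code, "general"), "not_evaluable")
})

test_that("BS2 follows the healthy-observation gate per scheme", {
  pop <- population_data(NULL, 0L, TRUE, flossies_count = 12L)
  res <- run_rules(av_fix(gene = "BRCA1", pop = pop),
                   hc_registry_fix$brca1)
  expect_identical(rule_status(res, "BS2", "general"),
                   "disabled_by_scheme")
  res <- run_rules(av_fix(gene = "CDH1", pop = pop),
                   hc_registry_fix$cdh1)
  expect_identical(rule_status(res, "BS2", "general"), "applied")
  pop9 <- population_data(NULL, 0L, TRUE, flossies_count = 9L)
  res <- run_rules(av_fix(gene = "CDH1", pop = pop9),
                   hc_registry_fix$cdh1)
  expect_identical(rule_status(res, "BS2", "general"), "not_applied")
})

test_that("computational criteria grade the scheme's single predictor", {
  tp53 <- hc_registry_fix$tp53
  # BayesDel above the supporting cut + benign SpliceAI
  av <- av_fix(gene = "TP53",
               scores = prediction_scores(bayesdel = 0.15,
                                          spliceai_max_delta = 0.01))
  res <- run_rules(av, tp53)
  pp3p <- get_result(res, "PP3", "protein")
  expect_identical(pp3p$status, "applied")
  expect_identical(pp3p$strength, "supporting")
  expect_identical(rule_status(res, "BP4", "splicing"), "applied")
  expect_identical(rule_status(res, "BP4", "protein"), "not_applied")

  # graded strength: strong cut reached
  av <- av_fix(gene = "TP53",
               scores = prediction_scores(bayesdel = 0.55,
                                          spliceai_max_delta = 0.01))
  expect_identical(get_result(run_rules(av, tp53), "PP3",
                              "protein")$strength, "strong")

  # synonymous with benign SpliceAI: BP7 + BP4(splicing); protein
  # channel not evaluable without a missense score
  av <- av_fix("synonymous",
               scores = prediction_scores(spliceai_max_delta = 0.02))
  res <- run_rules(av, hc_base)
  expect_identical(rule_status(res, "BP7", "splicing"), "applied")
  expect_identical(rule_status(res, "BP4", "splicing"), "applied")
  expect_identical(rule_status(res, "PP3", "protein"), "not_evaluable")
  expect_identical(rule_status(res, "BP4", "protein"), "not_evaluable")

  # missing SpliceAI: splicing-channel rules not evaluable
  av <- av_fix(gene = "ATM", scores = prediction_scores(revel = 0.7))
  res <- run_rules(av, hc_registry_fix$atm)
  for (code in c("PP3", "BP4"))
    expect_identical(rule_status(res, code, "splicing"), "not_evaluable")
  expect_identical(rule_status(res, "BP7", "splicing"), "not_evaluable")
})

test_that("the loss-of-function tree grades NMD, domains and truncation", {
  # NMD-competent nonsense: very strong
  av <- av_fix("nonsense", ptc_position = 300, protein_length = 800,
               last_junction_offset = -120)
  r <- get_result(run_rules(av, hc_base), "PVS1", "protein")
  expect_identical(r$strength, "very_strong")
  expect_match(r$comment, "NMD")

  # NMD escape in a critical domain: strong
  av <- av_fix("nonsense", ptc_position = 780, protein_length = 800,
               last_junction_offset = -20, is_last_exon = TRUE,
               prior = prior_classification(domain_overlap = TRUE))
  expect_identical(get_result(run_rules(av, hc_base), "PVS1",
                              "protein")$strength, "strong")

  # NMD escape removing > 10 % of the protein: strong
  av <- av_fix("nonsense", ptc_position = 600, protein_length = 800,
               last_junction_offset = -20, is_last_exon = TRUE)
  expect_identical(get_result(run_rules(av, hc_base), "PVS1",
                              "protein")$strength, "strong")

  # NMD escape, small distal truncation: moderate
  av <- av_fix("nonsense", ptc_position = 790, protein_length = 800,
               last_junction_offset = -10, is_last_exon = TRUE)
  expect_identical(get_result(run_rules(av, hc_base), "PVS1",
                              "protein")$strength, "moderate")

  # canonical donor, frame-disrupting with NMD: very strong (splicing)
  av <- av_fix("splice_donor", dist_to_splice_site = 1,
               splice_frame_disrupting = TRUE, splice_nmd = TRUE)
  expect_identical(get_result(run_rules(av, hc_base), "PVS1",
                              "splicing")$strength, "very_strong")

  # in-frame event without domain involvement: moderate
  av <- av_fix("splice_acceptor", dist_to_splice_site = -2,
               splice_frame_disrupting = FALSE)
  expect_identical(get_result(run_rules(av, hc_base), "PVS1",
                              "splicing")$strength, "moderate")

  # missing tree inputs are named
  av <- av_fix("nonsense")
  r <- get_result(run_rules(av, hc_base), "PVS1", "protein")
  expect_identical(r$status, "not_evaluable")
  expect_match(r$comment, "missing")
})

test_that("RNA evidence overrides predicted splice loss-of-function in BRCA", {
  av <- av_fix("splice_acceptor", gene = "BRCA1",
               dist_to_splice_site = -2,
               splice_frame_disrupting = TRUE, splice_nmd = TRUE,
               rna = rna_evidence("confirmed_normal_splicing"))
  r <- get_result(run_rules(av, hc_registry_fix$brca1), "PVS1", "splicing")
  expect_identical(r$status, "not_applied")
  expect_match(r$comment, "RNA")
  # same annotation under the base scheme (no RNA integration): applied
  r2 <- get_result(run_rules(av, hc_base), "PVS1", "splicing")
  expect_identical(r2$status, "applied")
})

test_that("same-change criteria separate protein and splicing evidence", {
  av <- av_fix(prior = prior_classification(same_aa_change = TRUE))
  res <- run_rules(av, hc_base)
  expect_identical(get_result(res, "PS1", "protein")$strength, "strong")
  expect_identical(rule_status(res, "PM5", "protein"), "not_applied")

  # spliceogenic prediction blocks protein-level PS1
  av <- av_fix(prior = prior_classification(same_aa_change = TRUE),
               scores = prediction_scores(spliceai_max_delta = 0.9))
  expect_identical(rule_status(run_rules(av, hc_base), "PS1", "protein"),
                   "not_applied")

  # same splice site with supporting prediction: PS1 splicing
  av <- av_fix("intronic", dist_to_splice_site = -5,
               prior = prior_classification(same_splice_site_pathogenic = TRUE),
               scores = prediction_scores(spliceai_max_delta = 0.9))
  r <- get_result(run_rules(av, hc_base), "PS1", "splicing")
  expect_identical(r$status, "applied")
  expect_identical(r$strength, "moderate")

  # PM5 without PS1
  av <- av_fix(prior = prior_classification(same_codon_other_aa = TRUE))
  res <- run_rules(av, hc_base)
  expect_identical(get_result(res, "PM5", "protein")$strength, "moderate")
  expect_identical(rule_status(res, "PS1", "protein"), "not_applied")
})

test_that("structural criteria follow region flags and scheme gates", {
  av <- av_fix("inframe_indel")
  res <- run_rules(av, hc_base)
  expect_identical(rule_status(res, "PM4", "protein"), "applied")
  expect_identical(rule_status(res, "BP3", "protein"), "not_applied")

  av_rep <- av_fix("inframe_indel",
                   prior = prior_classification(repeat_region = TRUE))
  res <- run_rules(av_rep, hc_base)
  expect_identical(rule_status(res, "PM4", "protein"), "not_applied")
  expect_identical(rule_status(res, "BP3", "protein"), "applied")
  # BP3 is not applicable under any gene-specific scheme
  res <- run_rules(av_rep, hc_registry_fix$palb2)
  expect_identical(rule_status(res, "BP3", "protein"),
                   "disabled_by_scheme")

  expect_identical(rule_status(run_rules(av_fix("stop_lost"), hc_base),
                               "PM4", "protein"), "applied")
  expect_identical(rule_status(run_rules(
    av_fix(prior = prior_classification(hotspot_overlap = TRUE)),
    hc_base), "PM1", "protein"), "applied")
  # gene-mechanism flags drive PP2/BP1
  expect_identical(rule_status(run_rules(av_fix(gene = "TP53"),
                                         hc_registry_fix$tp53),
                               "PP2", "protein"), "applied")
  expect_identical(rule_status(run_rules(av_fix(gene = "PALB2"),
                                         hc_registry_fix$palb2),
                               "BP1", "protein"), "applied")
})

test_that("functional-assay criteria are BRCA-only and strength-mapped", {
  av <- av_fix(gene = "BRCA1",
               assay = functional_assay("non_functional", "strong"))
  expect_identical(get_result(run_rules(av, hc_registry_fix$brca1),
                              "PS3", "general")$strength, "strong")
  av <- av_fix(gene = "BRCA2",
               assay = functional_assay("functional", "moderate"))
  expect_identical(get_result(run_rules(av, hc_registry_fix$brca2),
                              "BS3", "general")$strength, "moderate")
  av <- av_fix(gene = "ATM",
               assay = functional_assay("non_functional", "strong"))
  res <- run_rules(av, hc_registry_fix$atm)
  expect_identical(rule_status(res, "PS3", "general"),
                   "disabled_by_scheme")
  expect_identical(rule_status(res, "BS3", "general"),
                   "disabled_by_scheme")
})

test_that("cosegregation grades likelihood ratios in both directions", {
  av <- av_fix(coseg = cosegregation_data(likelihood_ratio = 20))
  expect_identical(get_result(run_rules(av, hc_base), "PP1",
                              "general")$strength, "strong")
  av <- av_fix(coseg = cosegregation_data(likelihood_ratio = 0.3))
  expect_identical(get_result(run_rules(av, hc_base), "BS4",
                              "general")$strength, "supporting")
  av <- av_fix(coseg = cosegregation_data(informative_meioses = 5L))
  expect_identical(get_result(run_rules(av, hc_base), "PP1",
                              "general")$strength, "moderate")
  av <- av_fix()
  res <- run_rules(av, hc_base)
  expect_identical(rule_status(res, "PP1", "general"), "not_evaluable")
  expect_identical(rule_status(res, "BS4", "general"), "not_evaluable")
  # contradictory LR and meioses
  av <- av_fix(coseg = cosegregation_data(likelihood_ratio = 0.1,
                                          informative_meioses = 7L))
  res <- run_rules(av, hc_base)
  expect_identical(rule_status(res, "PP1", "general"), "not_evaluable")
  expect_match(get_result(res, "PP1", "general")$comment, "contradictory")
})

test_that("run_rules is deterministic and covers all codes and channels", {
  av <- av_fix(pop = population_data(1e-3, 10L, TRUE))
  res1 <- run_rules(av, hc_base)
  res2 <- run_rules(av, hc_base)
  expect_identical(results_table(res1), results_table(res2))
  tab <- results_table(res1)
  expect_setequal(unique(tab$code), automated_codes())
  expect_identical(nrow(tab), 23L)  # 19 codes, 4 with dual channels
  # restriction: one evaluable code, all others disabled
  res <- run_rules(av, restrict_rules(hc_base, "BA1"))
  tab <- results_table(res)
  expect_identical(sum(tab$status != "disabled_by_scheme"), 1L)
  expect_identical(tab$code[tab$status != "disabled_by_scheme"], "BA1")
})

test_that("applied results mention their triggering evidence value", {
  av <- av_fix(gene = "TP53",
               pop = population_data(0.02, 100L, TRUE,
                                     flossies_count = 15L),
               scores = prediction_scores(bayesdel = 0.55,
                                          spliceai_max_delta = 0.3),
               coseg = cosegregation_data(likelihood_ratio = 400))
  res <- run_rules(av, hc_registry_fix$tp53)
  expect_match(get_result(res, "BA1", "general")$comment, "0.02")
  expect_match(get_result(res, "BS2", "general")$comment, "15")
  expect_match(get_result(res, "PP3", "protein")$comment, "0.55")
  expect_match(get_result(res, "PP3", "splicing")$comment, "0.3")
  expect_match(get_result(res, "PP1", "general")$comment, "400")
})

test_that("channel exclusivity and frequency monotonicity hold", {
  set.seed(7)
  afs <- c(0, sort(stats::runif(60)), 1,
           th_base$pm2_af, th_base$bs1_af, th_base$ba1_af)
  patho_rank <- function(res) {
    # higher = more pathogenic population call
    if (rule_status(res, "BA1", "general") == "applied") return(0)
    if (rule_status(res, "BS1", "general") == "applied") return(1)
    if (rule_status(res, "PM2", "general") == "applied") return(3)
    2
  }
  ranks <- vapply(sort(afs, decreasing = TRUE), function(af) {
    patho_rank(run_rules(av_fix(pop = population_data(af, 10L, TRUE)),
                         hc_base))
  }, numeric(1))
  expect_true(all(diff(ranks) >= 0))  # AF decreasing => never less benign

  for (i in 1:200) {
    sc <- prediction_scores(revel = stats::runif(1),
                            spliceai_max_delta = stats::runif(1))
    res <- run_rules(av_fix(scores = sc,
                            pop = population_data(stats::runif(1), 5L,
                                                  TRUE)), hc_base)
    for (ch in c("protein", "splicing"))
      expect_false(rule_status(res, "PP3", ch) == "applied" &&
                     rule_status(res, "BP4", ch) == "applied")
    expect_false(rule_status(res, "BA1", "general") == "applied" &&
                   rule_status(res, "BS1", "general") == "applied")
    expect_false(rule_status(res, "PS1", "protein") == "applied" &&
                   rule_status(res, "PM5", "protein") == "applied")
  }
})

test_that("engine results match the straight-line oracle on random variants", {
  spec <- fixture_spec(seed = 303L, n = 300L)
  cohort <- with(list(), {
    tmp <- tempfile(fileext = ".jsonl")
    on.exit(unlink(c(tmp, paste0(tmp, ".expected.jsonl"))))
    generate_cohort(spec, tmp)
  })
  res <- replay_cohort(cohort$variants, cohort$expected, hc_registry_fix)
  if (nrow(res$mismatches)) print(utils::head(res$mismatches, 20))
  expect_identical(res$n_concordant, res$n)
})
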
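test_that("the automated registry holds exactly the 19 documented codes", {
  codes <- automated_codes()
  expect_length(codes, 19)
  expect_setequal(codes,
                  c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM4", "PM5",
                    "PP1", "PP2", "PP3", "BA1", "BS1", "BS2", "BS3",
                    "BS4", "BP1", "BP3", "BP4", "BP7"))
  # complement within the 28 criteria, by unavailable-evidence category
  ex <- excluded_criteria()
  expect_setequal(ex$code[ex$category == "de_novo"], c("PS2", "PM6"))
  expect_setequal(ex$code[ex$category == "allelic"],
                  c("PM3", "BP2", "BP5"))
  expect_identical(ex$code[ex$category == "phenotype"], "PP4")
  expect_identical(ex$code[ex$category == "case_control"], "PS4")
  expect_setequal(ex$code[ex$category == "reputable_source"],
                  c("PP5", "BP6"))
  expect_length(union(codes, ex$code), 28)
})

test_that("every shipped scheme loads and satisfies its invariants", {
  reg <- hc_registry_fix
  expect_setequal(names(reg),
                  c("acmg_base", "atm", "brca1", "brca2", "cdh1",
                    "palb2", "pten", "tp53"))
  for (s in reg) {
    th <- s$thresholds
    expect_true(th$ba1_af > th$bs1_af)
    expect_true(th$bs1_af > th$pm2_af)
    expect_true(th$spliceai_pathogenic > th$spliceai_benign)
  }
  # predictor selection: BayesDel for BRCA1/BRCA2/TP53, REVEL otherwise
  expect_identical(reg$brca1$pathogenicity_tool, "bayesdel")
  expect_identical(reg$brca2$pathogenicity_tool, "bayesdel")
  expect_identical(reg$tp53$pathogenicity_tool, "bayesdel")
  expect_identical(reg$cdh1$pathogenicity_tool, "revel")
  expect_identical(reg$atm$pathogenicity_tool, "revel")
  # BS2 gate
  for (id in c("brca1", "brca2", "palb2", "pten"))
    expect_false(reg[[id]]$bs2_allowed)
  expect_true(reg$cdh1$bs2_allowed)
  expect_true(reg$tp53$bs2_allowed)
  # functional-assay gate and BP3 applicability
  for (id in names(reg)) {
    expect_identical(reg[[id]]$functional_rules_allowed,
                     id %in% c("brca1", "brca2"))
    expect_identical(reg[[id]]$bp3_applicable, id == "acmg_base")
  }
})

test_that("scheme selection dispatches by gene, case-insensitively", {
  expect_identical(select_scheme("TP53", hc_registry_fix)$scheme_id, "tp53")
  expect_identical(select_scheme("brca2", hc_registry_fix)$scheme_id,
                   "brca2")
  for (g in c("CHEK2", "MSH2", "RAD51D", "PMS2", "BRIP1"))
    expect_identical(select_scheme(g, hc_registry_fix)$scheme_id,
                     "acmg_base")
  expect_identical(select_scheme(NA, hc_registry_fix)$scheme_id,
                   "acmg_base")
})

test_that("rule restriction intersects and rejects unknown codes", {
  all_sel <- restrict_rules(hc_base, automated_codes())
  expect_setequal(all_sel$enabled_rules, hc_base$enabled_rules)
  only_ba1 <- restrict_rules(hc_base, "BA1")
  expect_identical(only_ba1$enabled_rules, "BA1")
  expect_error(restrict_rules(hc_base, c("BA1", "PS4")),
               class = "UNKNOWN_RULE")
  expect_error(restrict_rules(hc_base, "PP5"), class = "UNKNOWN_RULE")
})

test_that("config loading rejects unknown keys and broken invariants", {
  dir <- withr::local_tempdir()
  file.copy(file.path(default_config_dir(), "defaults.yaml"), dir)
  writeLines(c("scheme_id: acmg_base", "version_label: x", "typo_key: 1"),
             file.path(dir, "acmg_base.yaml"))
  expect_error(load_scheme("acmg_base", dir), class = "CONFIG_INVALID")

  # missing required keys
  writeLines(c("scheme_id: acmg_base", "version_label: x"),
             file.path(dir, "acmg_base.yaml"))
  expect_error(load_scheme("acmg_base", dir), class = "CONFIG_INCOMPLETE")

  # frequency-cut ordering violated via overrides
  ov <- file.path(dir, "bad_profile.yaml")
  writeLines(c("thresholds:", "  ba1_af: 1.0e-09"), ov)
  expect_error(load_scheme("acmg_base", default_config_dir(),
                           overrides_file = ov),
               class = "CONFIG_INVALID")
})

test_that("the literal allele-frequency profile loads and reorders cuts", {
  prof <- file.path(default_config_dir(), "profiles", "af_literal.yaml")
  s <- load_scheme("acmg_base", overrides_file = prof)
  expect_equal(s$thresholds$ba1_af, 1e-5)
  expect_equal(s$thresholds$bs1_af, 1e-6)
})
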
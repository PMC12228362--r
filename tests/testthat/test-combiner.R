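test_that("channel selection combines general with channel evidence", {
  results <- list(
    rule_result("BA1", "general", "applied", "stand_alone", "AF 0.02"),
    rule_result("PP3", "protein", "applied", "supporting", "score"),
    rule_result("PP3", "splicing", "applied", "supporting", "delta"),
    rule_result("BS1", "general", "not_applied", comment = "band"))
  spl <- channel_select(results, "splicing")
  expect_setequal(spl$code, c("BA1", "PP3"))
  prot <- channel_select(results, "protein")
  expect_setequal(prot$code, c("BA1", "PP3"))
  # splicing-only evidence leaves only general rules for protein
  spl_only <- list(rule_result("BP7", "splicing", "applied", "supporting",
                               "syn"),
                   rule_result("PM2", "general", "applied", "supporting",
                               "absent"))
  expect_identical(channel_select(spl_only, "protein")$code, "PM2")
  expect_identical(nrow(channel_select(list(), "protein")), 0L)
})

test_that("the class-combining rules reproduce the published table", {
  expect_identical(classify_acmg_combining(applied_df(character(),
                                                      character())),
                   "vus")
  expect_identical(
    classify_acmg_combining(applied_df("BA1", "stand_alone")), "benign")
  expect_identical(
    classify_acmg_combining(applied_df(c("PVS1", "PS1"),
                                       c("very_strong", "strong"))),
    "pathogenic")
  expect_identical(
    classify_acmg_combining(applied_df(c("PVS1", "PM2"),
                                       c("very_strong", "moderate"))),
    "likely_pathogenic")
  expect_identical(
    classify_acmg_combining(applied_df(c("BS1", "BP4"),
                                       c("strong", "supporting"))),
    "likely_benign")
  expect_identical(
    classify_acmg_combining(applied_df(c("BS1", "BS2"),
                                       c("strong", "strong"))), "benign")
  # conflicting sides resolve to VUS
  expect_identical(
    classify_acmg_combining(applied_df(c("PVS1", "PS1", "BS1", "BS2"),
                                       c("very_strong", "strong",
                                         "strong", "strong"))), "vus")
})

test_that("point-based classification sums and maps onto class bounds", {
  expect_identical(classify_point_based(applied_df(character(),
                                                   character())),
                   list(point_score = 0L, point_class = "vus"))
  r <- classify_point_based(applied_df(c("PVS1", "PM2"),
                                       c("very_strong", "supporting")))
  expect_identical(r$point_score, 9L)
  expect_identical(r$point_class, "likely_pathogenic")
  r <- classify_point_based(applied_df(c("BS1", "BP4", "BP7"),
                                       c("strong", "supporting",
                                         "supporting")))
  expect_identical(r$point_score, -6L)
  expect_identical(r$point_class, "likely_benign")
  r <- classify_point_based(applied_df(c("BS1", "BS2"),
                                       c("strong", "strong")))
  expect_identical(r$point_class, "benign")
  # BA1 short-circuit dominates any pathogenic sum
  r <- classify_point_based(applied_df(c("BA1", "PVS1", "PS1"),
                                       c("stand_alone", "very_strong",
                                         "strong")))
  expect_identical(r$point_class, "benign")
})

test_that("point classification is monotone under added pathogenic evidence", {
  set.seed(11)
  codes_p <- c("PVS1", "PS1", "PM2", "PP3")
  str_p <- c("very_strong", "strong", "moderate", "supporting")
  cls <- hc_classes()
  for (i in 1:300) {
    n <- sample(0:5, 1)
    idx <- sample(4, n, replace = TRUE)
    base_set <- applied_df(codes_p[idx], str_p[idx])
    nb <- sample(0:3, 1)
    bidx <- sample(3, nb, replace = TRUE)
    base_set <- rbind(base_set,
                      applied_df(c("BS1", "BP4", "BP7")[bidx],
                                 c("strong", "supporting",
                                   "supporting")[bidx]))
    before <- classify_point_based(base_set)
    add <- sample(4, 1)
    after <- classify_point_based(rbind(base_set,
                                        applied_df(codes_p[add],
                                                   str_p[add])))
    expect_gte(after$point_score, before$point_score)
    expect_gte(match(after$point_class, cls),
               match(before$point_class, cls))
  }
})

test_that("channel merge follows the two quoted constraints and symmetry", {
  expect_identical(merge_channels("vus", "likely_pathogenic"),
                   "likely_pathogenic")
  expect_identical(merge_channels("likely_benign", "pathogenic"), "vus")
  expect_identical(merge_channels("likely_benign", "benign"), "benign")
  expect_identical(merge_channels("vus", "vus"), "vus")
  cls <- hc_classes()
  side <- function(x) if (x %in% c("benign", "likely_benign")) -1
                      else if (x == "vus") 0 else 1
  for (a in cls) for (b in cls) {
    m <- merge_channels(a, b)
    expect_identical(m, merge_channels(b, a))
    if (a == "vus") expect_identical(m, b)
    if (a != "vus" && b != "vus" && side(a) != side(b))
      expect_identical(m, "vus")
    expect_identical(m, oracle_merge_pair(a, b))
  }
})

test_that("rule-call summary uses OR for pathogenic, AND for benign", {
  mk <- function(...) list(...)
  res <- mk(
    rule_result("PP3", "protein", "applied", "supporting", "score"),
    rule_result("PP3", "splicing", "not_applied", comment = "delta low"),
    rule_result("BP4", "protein", "applied", "supporting", "score"),
    rule_result("BP4", "splicing", "not_applied", comment = "delta high"),
    rule_result("PVS1", "protein", "not_applied", comment = "csq"),
    rule_result("PVS1", "splicing", "applied", "very_strong", "skip"),
    rule_result("BA1", "general", "applied", "stand_alone", "AF"))
  calls <- summarize_rule_calls(res)
  expect_true(calls[["PP3"]])    # either channel suffices
  expect_false(calls[["BP4"]])   # both channels required
  expect_true(calls[["PVS1"]])
  expect_true(calls[["BA1"]])
  expect_false(calls[["PM2"]])
  # benign dual-channel code applied in both channels is called
  res2 <- mk(
    rule_result("BP4", "protein", "applied", "supporting", "score"),
    rule_result("BP4", "splicing", "applied", "supporting", "delta"))
  expect_true(summarize_rule_calls(res2)[["BP4"]])
})

test_that("reports are internally consistent and recomputable", {
  av <- av_fix(gene = "BRCA1", consequence = "nonsense",
               ptc_position = 300, protein_length = 800,
               last_junction_offset = -120,
               pop = population_data(NULL, 0L, TRUE))
  rep <- classify_variant(av, hc_registry_fix$brca1)
  expect_identical(rep$final_class,
                   merge_channels(rep$protein$point_class,
                                  rep$splicing$point_class))
  # recomputing the channel classes from all_results reproduces them
  for (ch in c("protein", "splicing")) {
    applied <- channel_select(rep$all_results, ch)
    expect_identical(classify_point_based(applied)$point_score,
                     rep[[ch]]$point_score)
    expect_identical(classify_acmg_combining(applied),
                     rep[[ch]]$acmg_class)
  }
})
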
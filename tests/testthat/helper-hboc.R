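# Shared fixtures and independent oracles for the suite. The oracles
# here (normalization enumeration, combining truth table) are coded
# from first principles and share no logic with the package internals.

hc_registry_fix <- scheme_registry()
hc_base <- hc_registry_fix$acmg_base

av_fix <- function(consequence = "missense", gene = "CHEK2",
                   pop = population_data(),
                   scores = prediction_scores(),
                   prior = prior_classification(),
                   assay = functional_assay(),
                   coseg = cosegregation_data(),
                   rna = rna_evidence(), ...) {
  tx <- transcript_annotation(consequence = consequence, exon_index = 3,
                              total_exons = 12, ...)
  annotated_variant(variant_record("17", 43100000L, "G", "A", gene = gene),
                    tx, pop, scores, prior, assay, coseg, rna)
}

get_result <- function(results, code, channel) {
  for (r in results)
    if (r$code == code && r$channel == channel) return(r)
  NULL
}

rule_status <- function(results, code, channel) {
  get_result(results, code, channel)$status
}

# --- brute-force normalization oracle -------------------------------
# Applies a variant to the context window and returns the haplotype.
apply_variant <- function(seq, window_start, pos, ref, alt) {
  i <- pos - window_start + 1
  stopifnot(substr(seq, i, i + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, i - 1), alt,
         substr(seq, i + nchar(ref), nchar(seq)))
}

# Enumerates every representation inside the window whose applied
# haplotype equals the input's; returns the parsimonious (minimal total
# allele length) left-most one.
normalize_oracle <- function(seq, window_start, pos, ref, alt) {
  target <- apply_variant(seq, window_start, pos, ref, alt)
  n <- nchar(seq)
  best <- NULL
  for (p in window_start:(window_start + n - 1)) {
    i <- p - window_start + 1
    pre <- substr(seq, 1, i - 1)
    if (substr(target, 1, i - 1) != pre) next
    for (rl in 1:(n - i + 1)) {
      r2 <- substr(seq, i, i + rl - 1)
      post <- substr(seq, i + rl, n)
      al <- nchar(target) - nchar(pre) - nchar(post)
      if (al < 1) next
      if (substr(target, nchar(target) - nchar(post) + 1,
                 nchar(target)) != post) next
      a2 <- substr(target, i, i + al - 1)
      if (r2 == a2) next
      cand <- list(pos = p, ref = r2, alt = a2,
                   len = rl + al)
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$pos < best$pos))
        best <- cand
    }
  }
  best
}

random_indel_case <- function() {
  n <- 60L
  seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
  window_start <- sample.int(1000, 1) + 100L
  off <- sample(25:45, 1)
  pos <- window_start + off
  kind <- sample(c("snv", "del", "ins", "mnv"), 1)
  i <- off + 1L
  ref <- switch(kind,
    snv = substr(seq, i, i),
    del = substr(seq, i, i + sample.int(6, 1)),
    ins = substr(seq, i, i),
    mnv = substr(seq, i, i + sample.int(3, 1)))
  alt <- switch(kind,
    snv = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
    del = substr(ref, 1, 1),
    ins = paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                   sample.int(5, 1), replace = TRUE),
                            collapse = "")),
    mnv = paste(sample(c("A", "C", "G", "T"), nchar(ref) +
                         sample(-1:1, 1), replace = TRUE), collapse = ""))
  if (ref == alt) return(NULL)
  if (grepl("[^ACGT]", alt) || nchar(alt) == 0) return(NULL)
  list(seq = seq, window_start = window_start, pos = pos,
       ref = ref, alt = alt)
}

# --- independent class-combining truth table ------------------------
# Straight re-encoding of the published combination rules on counts of
# applied strengths (pvs/ps/pm/pp pathogenic; ba/bs/bp benign, where
# very-strong benign counts as strong and moderate benign as
# supporting).
combine_truth_table <- function(pvs, ps, pm, pp, ba, bs, bp) {
  if (ba > 0) return("benign")
  path <- FALSE
  if (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2))
    path <- TRUE
  if (ps >= 2) path <- TRUE
  if (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
    path <- TRUE
  lpath <- (pvs == 1 && pm == 1) ||
    (ps == 1 && (pm == 1 || pm == 2)) ||
    (ps == 1 && pp >= 2) ||
    (pm >= 3) || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)
  ben <- bs >= 2
  lben <- (bs == 1 && bp == 1) || bp >= 2
  if ((path || lpath) && (ben || lben)) return("vus")
  if (path) return("pathogenic")
  if (lpath) return("likely_pathogenic")
  if (ben) return("benign")
  if (lben) return("likely_benign")
  "vus"
}

# Build a channel_select-style applied data frame from code/strength
# pairs, inferring direction from the code prefix.
applied_df <- function(codes, strengths) {
  data.frame(code = as.character(codes), strength = as.character(strengths),
             direction = as.character(ifelse(substr(codes, 1, 1) == "B",
                                             "benign", "pathogenic")),
             stringsAsFactors = FALSE)
}

# Independent merge rule, derived directly from the two constraints
# (one VUS -> the other class; opposite sides -> VUS) plus the
# more-extreme-tier convention for same-side pairs.
oracle_merge_pair <- function(a, b) {
  side <- function(x) if (x %in% c("benign", "likely_benign")) -1L
                      else if (x == "vus") 0L else 1L
  extremity <- function(x) switch(x, benign = 2L, likely_benign = 1L,
                                  vus = 0L, likely_pathogenic = 1L,
                                  pathogenic = 2L)
  if (side(a) == 0L) return(b)
  if (side(b) == 0L) return(a)
  if (side(a) != side(b)) return("vus")
  if (extremity(a) >= extremity(b)) a else b
}
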
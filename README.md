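# hbocclassify

Automated ACMG/AMP germline variant classification for hereditary
breast and ovarian cancer (HBOC) genes, in R.

Clinical variant classification combines many evidence types —
population frequency, in-silico prediction, prior classifications,
functional assays, cosegregation — under the 28 ACMG/AMP criteria and,
increasingly, under gene-specific ClinGen specifications. Doing this by
hand is slow and inconsistent between assessors. `hbocclassify` is a
rule engine for the part of that process that machine-readable evidence
can drive: it evaluates the 19 automatable criteria on pre-annotated
small variants (≤ 15 bp), under the base ACMG/AMP scheme or
gene-specific schemes for *ATM*, *BRCA1*, *BRCA2*, *CDH1*, *PALB2*,
*PTEN* and *TP53*, and reports every rule's status with an explanatory
comment. It is aimed at clinical scientists and tool builders who need
reproducible, auditable criterion preselection — not a replacement for
expert review.

## The model

Each criterion carries a direction (pathogenic/benign), an evidence
strength (supporting, moderate, strong, very strong, or stand-alone),
and an **evidence channel**: `general`, `protein`, or `splicing`.
Evidence for a protein-level effect and for a splicing-level effect is
kept strictly separate: the engine produces **two classifications per
variant**, combining `general + protein` evidence and
`general + splicing` evidence respectively. Criteria with splicing-aware
implementations (PVS1, PS1, PP3, BP4, BP7) contribute to their own
channel only.

Within each channel, two combination systems run side by side:

- the **original class-combining rules** on counts of applied strengths
  (e.g. pathogenic if 1 very-strong + ≥ 1 strong, …; benign if BA1 or
  ≥ 2 strong benign);
- the **point-based system**: supporting = 1, moderate = 2, strong = 4,
  very strong = 8 points, negated for benign criteria, with class
  bounds ≥ +10 pathogenic, +6…+9 likely pathogenic, 0…+5 VUS, −6…−1
  likely benign, ≤ −7 benign. BA1 (stand-alone) short-circuits to
  benign.

The two channel classes are then merged into one final class: if one
channel is VUS the other wins; a benign-side class meeting a
pathogenic-side class yields VUS; same-side classes merge to the more
extreme tier.

Key criterion behaviors: PM2 is applied at the downgraded *supporting*
strength; BS2 uses counts from a cancer-free aged-women resource
(FLOSSIES) and is unavailable under the *BRCA1*/*BRCA2*/*PALB2*/*PTEN*
schemes; PS3/BS3 are automated only for *BRCA1*/*BRCA2*; BP3 is not
applicable under any gene-specific scheme; the single-predictor policy
uses SpliceAI for splicing everywhere and REVEL for protein impact
except *BRCA1*/*BRCA2*/*TP53*, which use BayesDel. All thresholds live
in YAML configuration (`inst/config/`), never in code.

## Worked example

```r
library(hbocclassify)
vs <- read_annotated_json(system.file("extdata",
        "synthetic_example_variants.jsonl", package = "hbocclassify"))
classify_variant(vs[[1]])   # BRCA1 frameshift, NM_007294.4:c.1175del
```

```
ACMG/AMP classification (scheme: brca1)
  protein:  likely_pathogenic (points +9, combining vus)
  splicing: vus (points +0, combining vus)
  final:    likely_pathogenic (merged points classes)
  called criteria: PVS1, PM2
```

The frameshift introduces an NMD-competent premature stop (PVS1 very
strong, +8) and is absent from the population resource at adequate
coverage (PM2 supporting, +1): 9 points, likely pathogenic on protein
evidence. The splicing channel has no applicable evidence, so the final
class is the protein-channel call. The per-rule audit trail is in the
report:

```r
results_table(classify_variant(vs[[1]])$all_results)[1:3, ]
#>   code  channel      status    strength  comment
#> 1 PVS1  protein     applied very_strong  frameshift with NMD-competent PTC (offset -3200 nt ...)
#> 2 PVS1 splicing not_applied        <NA>  consequence frameshift is not a canonical splice-site variant
#> 3  PS1  protein not_applied        <NA>  no established pathogenic variant with the identical amino-acid change
```

A common missense variant (`vs[[4]]`, popmax AF 0.4 %) instead hits the
BA1 stand-alone frequency criterion and short-circuits to benign in
both channels.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/hboc-classify classify \
  --input inst/extdata/synthetic_example_variants.jsonl \
  --out report.json            # or --output vcf
```

## Synthetic fixtures and the expectation oracle

`generate_cohort()` produces seeded, deterministic cohorts of annotated
variants whose evidence grids straddle every configured threshold,
together with an expectations sidecar computed by an independent
straight-line re-implementation of every rule
(`oracle_expectations()`). `replay_cohort()` feeds the cohort through
the engine and compares. `generate_rule_fixture()` builds minimal
triggering/non-triggering pairs per criterion.

## Scope and limitations

Variants larger than 15 bp (measured on the longer allele after left
normalization), structural and copy-number variants, and somatic
classification are out of scope. Inputs must be pre-annotated GRCh38
records (JSON Lines; see `inst/schema/annotated_variant.schema.json`);
the package performs no annotation, liftover or HGVS parsing. See the
methods vignette (`vignettes/classification-methods.Rmd`) for the full
model description, threshold provenance and design decisions.
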
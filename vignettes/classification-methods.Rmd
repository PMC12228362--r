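---
title: "Methods: channelled ACMG/AMP classification for HBOC genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channelled ACMG/AMP classification for HBOC genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbocclassify)
```

## Overview

`hbocclassify` evaluates the automatable subset of the ACMG/AMP
germline classification criteria on pre-annotated small variants in
hereditary breast and ovarian cancer genes. This vignette documents the
model, the configurable parameters and their provenance, the numerical
and design choices that were genuinely open, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The criterion registry

Of the 28 ACMG/AMP criteria, 19 can be driven by machine-readable
evidence and form the automated registry: PVS1, PS1, PS3, PM1, PM2,
PM4, PM5, PP1, PP2, PP3 (pathogenic) and BA1, BS1, BS2, BS3, BS4, BP1,
BP3, BP4, BP7 (benign). The other nine are excluded because their
evidence is not machine-readable at scale: de novo observations (PS2,
PM6), allelic data (PM3, BP2, BP5), phenotype specificity (PP4) and
case-control enrichment (PS4); PP5 and BP6 (reputable-source
assertions) are additionally registered but disabled everywhere,
following the recommendation to discontinue them. `excluded_criteria()`
documents this derivation; note that PP1 and BS4 are in the automated
set — they are evaluable whenever cosegregation statistics are supplied,
even though such data is often unavailable in practice.

Every criterion carries an evidence channel. `general` evidence
(frequency, assays, cosegregation) feeds both classifications; PVS1,
PS1, PP3 and BP4 have separate `protein` and `splicing`
implementations, PM1/PM4/PM5/PP2/BP1/BP3 are protein-only and BP7 is
splicing-only. The engine returns one result per criterion and channel
(23 results), each with a status (`applied`, `not_applied`,
`not_evaluable`, `disabled_by_scheme`) and a comment that names the
triggering evidence value — the audit trail is part of the contract.

## Input model

The engine consumes `annotated_variant` records and performs no
annotation itself. All transcript-level facts the loss-of-function tree
needs are precomputed into the record: the consequence call, the PTC
position, the signed distance of the variant/PTC from the last
exon–exon junction, the protein length, and — for canonical ±1/2
splice-site variants — a precomputed frame/NMD call for the predicted
aberrant transcript (`splice_frame_disrupting`, `splice_nmd`). This
keeps the engine free of transcript databases and makes every decision
reproducible from the record alone. The cost is that annotation quality
is the caller's responsibility.

Curation accepts a variant only if its stated reference allele matches
the supplied reference window, left-normalizes it to the minimal
left-most representation (shared-suffix trim, shared-prefix trim,
leftward shift through repeat tracts), and applies the scope gate:
variants above 15 bp are out of scope. The bound is read as inclusive
and measured on the longer allele *after* normalization — the stable
choice, since padded representations of small variants would otherwise
be rejected arbitrarily. GRCh37 input is not lifted over; HGVS strings
are carried as annotation, never parsed.

## Schemes and thresholds

Eight schemes ship as YAML (`inst/config/`): the base ACMG/AMP scheme
and gene-specific schemes for ATM (v1.3.0), BRCA1 (v1.1.0), BRCA2
(v1.1.0), CDH1 (v3.1.0), PALB2 (v1.1.0), PTEN (v3.1.0) and TP53
(v1.4.0). Scheme selection is by gene symbol, case-insensitive, with
the base scheme as fallback (e.g. CHEK2, MSH2, RAD51D, PMS2, BRIP1).
Structural gates are validated at load time:

- BS2 (healthy-observation counts, FLOSSIES-style resource) is not
  admitted under BRCA1, BRCA2, PALB2 or PTEN;
- PS3/BS3 (functional assays) are automated only for BRCA1 and BRCA2,
  where curated assay data exists;
- BP3 is not applicable under any gene-specific scheme;
- BayesDel is the pathogenicity predictor for BRCA1, BRCA2 and TP53,
  REVEL elsewhere; SpliceAI is the splicing predictor everywhere
  (single-predictor policy).

Every number lives in configuration, with the following defaults and
units:

| Parameter | Default | Meaning |
|---|---|---|
| `ba1_af` | 1e-3 | popmax AF above which BA1 (stand-alone) applies |
| `bs1_af` | 1e-4 | popmax AF above which BS1 applies (up to `ba1_af`) |
| `pm2_af` | 1e-5 | popmax AF below which (or absent) PM2 applies |
| REVEL cuts | 0.644/0.773/0.932 | supporting/moderate/strong pathogenic (≥) |
| REVEL benign cuts | 0.290/0.183/0.016 | supporting/moderate/strong benign (≤) |
| BayesDel cuts | 0.13/0.27/0.50 | pathogenic (≥) |
| BayesDel benign cuts | −0.18/−0.36 | supporting/moderate benign (≤) |
| `spliceai_pathogenic` | 0.2 | max delta at/above which splicing PP3 applies |
| `spliceai_benign` | 0.1 | max delta at/below which splicing BP4/BP7 apply |
| `bs2_count_min` | 10 | healthy-observation count for BS2 |
| PP1 LR cuts | 2.08/4.33/18.7/350 | cosegregation Bayes factors per strength |
| BS4 LR cuts | 0.48/0.23/0.053 | reciprocal benign cuts |
| PP1 meioses cuts | 3/5/7 | fallback when only meioses counts exist |
| points | 1/2/4/8 | supporting/moderate/strong/very strong |
| point bounds | +10/+6/−7 | pathogenic / likely-pathogenic / benign edges |

The allele-frequency and predictor cuts follow the published ClinGen
gene-specific specifications and calibrated-evidence recommendations;
the point constants and class bounds follow the Bayesian points
framework. An alternative frequency profile
(`inst/config/profiles/af_literal.yaml`, BA1 1e-5 / BS1 1e-6) is
shipped for users who want the far stricter calibration sometimes
quoted as "0.001 % / 0.0001 %"; with it, common-variant calls in
moderate-risk genes become markedly more permissive toward benign,
which is visible in discordance analyses. PM2 applies at the
downgraded *supporting* strength by default (`pm2_strength`),
reflecting current guidance.

Boundary semantics are fixed and pinned by tests whose probes sit
exactly on each cut: BA1/BS1 are strict (`>`), PM2 strict (`<`),
predictor and cosegregation cuts inclusive (`>=`/`<=`), SpliceAI
pathogenic inclusive (`>=`) and benign inclusive (`<=`).

## The loss-of-function tree (PVS1)

Protein channel, nonsense/frameshift: a PTC outside the last exon and
≥ 50 nt upstream of the last exon–exon junction is NMD-competent →
very strong. NMD escape downgrades: strong if the truncation removes a
functionally critical region or more than 10 % of the protein,
moderate otherwise. Start-loss is moderate (supporting when the scheme
flags an annotated alternative in-frame start). Splicing channel,
canonical ±1/2 variants: frame-disrupting event with NMD → very
strong; frame-disrupting NMD-escape in a critical region → strong;
in-frame loss overlapping a critical region → strong; otherwise
moderate. A frame-disrupting NMD-escape event outside any critical
region defaults to moderate: no removed-length estimate exists for a
predicted event, so the >10 % branch of the protein tree has no
splicing analogue. Under the BRCA1/BRCA2 schemes RNA evidence is
integrated: confirmed normal splicing forces the splicing-channel PVS1
to `not_applied`; confirmed aberrant splicing pins the predicted event
as observed (the comment says which). Missing tree inputs yield
`not_evaluable` with the missing fields named.

## Combination and merge

Per channel, applied `general` evidence joins the channel's own
evidence (a code applied in both contributes once, at the stronger
strength) and feeds two systems. The class-combining rules implement
the published combination table on counts of applied strengths;
because strength modulation can produce benign evidence at strengths
the original table never anticipated, benign very-strong counts with
the strong criteria and benign moderate with the supporting criteria.
Simultaneous qualification on both sides is a conflict and yields VUS.
The point system sums signed points and maps onto the configured
bounds. BA1 short-circuits both systems to benign with no rescue
mechanism — stand-alone semantics.

The final class merges the two channels (point classes by default,
configurable to the combining classes): one VUS → the other class;
opposite sides → VUS; same side → the more extreme tier. The
more-extreme choice for same-side pairs is a package decision — only
the VUS and opposite-side cases are externally constrained — and is
locked by an exhaustive 25-pair test. For cross-channel *rule-level*
summaries (`summarize_rule_calls()`), a dual-implementation pathogenic
criterion counts as called if either channel applied it; a benign one
only if both did.

## Synthetic data and the expectation oracle

`generate_cohort()` draws variants with evidence grids that straddle
every configured threshold and include the exact cut values, across all
consequence types, the seven scheme genes and five base-scheme genes.
Field probabilities (70 % of variants frequency-observed, 85 %
SpliceAI-scored, 25 % assayed, 45 % with cosegregation data, low rates
for prior-classification flags) were chosen once to make every
criterion fire with useful frequency in a 2,000-record cohort; they are
not calibrated to any real database. The generator emulates *marginal*
evidence availability only — it does not reproduce gnomAD/ClinVar
score distributions, linkage between fields (e.g. correlated REVEL and
BayesDel), or realistic per-gene variant spectra. Passing the replay
test therefore demonstrates that the engine implements its stated
decision logic exactly, not that it reproduces any external dataset's
classifications.

Expectations are computed by `oracle_expectations()`, a deliberately
flat re-implementation of every predicate, the combiners and the merge
table that shares no code with the engine; `replay_cohort()` compares
engine output against it field by field (every rule status and
strength, both channel classes under both systems, both point scores,
final class). The acceptance checks replay a seeded 2,000-variant
cohort at 100 % required concordance, verify the class-combining
implementation against an independent truth table over all ~1.8×10^5
criteria multisets of size ≤ 6, and exercise normalization idempotence
and haplotype preservation on 10,000 random indels in 60-nt windows —
sizes chosen to give dense boundary coverage while keeping a full run
in the minutes range on one core.

## Numerical and degenerate-input choices

- Left normalization follows the trim/extend algorithm that yields the
  unique parsimonious left-aligned representation; it is idempotent,
  and a unit test checks it against a brute-force enumeration of all
  equivalent representations in the window (parsimony first, then
  left-most — any representation can be padded leftward, so position
  alone is not a well-ordering).
- Insufficient upstream context to complete a shift raises
  `CTX_TOO_SHORT` rather than returning a partially shifted record.
- Records missing the population block default conservatively (no
  frequency data, coverage inadequate → frequency criteria
  `not_evaluable`) with a warning; `--strict` makes any deviation
  fatal.
- Contradictory cosegregation inputs (benign-range LR together with a
  pathogenic-range meioses count) render PP1 and BS4 `not_evaluable`
  with an explanatory comment rather than picking a side.
- PS1-splicing strength is `moderate` by default (configurable): the
  same-site prior plus a concordant prediction is weaker than an
  identical-nucleotide match.
- BP7 requires the variant not to sit at the canonical ±1/2 positions
  and, per configuration, extends to intronic variants beyond them.

## Limitations

Classification quality is bounded by the annotations supplied; the
engine trusts precomputed flags (hotspot, domain, repeat, frame/NMD)
without re-deriving them. RNA integration is reduced to a three-state
flag rather than quantitative splice-fraction evidence. PP2/BP1 depend
on per-scheme gene-mechanism flags that are editable configuration, not
curated constraints. The engine classifies one variant at a time: no
multi-variant phasing, no allelic criteria, no multifactorial
likelihood integration. These are deliberate scope boundaries, not
backlog items.
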
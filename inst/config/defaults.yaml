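# Shared defaults for every classification scheme. Every numeric
# constant the engine consumes lives here (or in a scheme file), never
# in code, so alternative calibrations can be swapped in.

# Additive point constants and class bounds of the point-based system
# (Tavtigian-style Bayesian points framework).
points:
  supporting: 1
  moderate: 2
  strong: 4
  very_strong: 8

# Class bounds on the summed points: >= pathogenic_min -> pathogenic;
# likely_pathogenic_min..pathogenic_min-1 -> likely pathogenic;
# 0..likely_pathogenic_min-1 -> VUS; benign_max+1..-1 -> likely benign;
# <= benign_max -> benign.
point_class_bounds:
  pathogenic_min: 10
  likely_pathogenic_min: 6
  benign_max: -7

thresholds:
  # Popmax allele-frequency cuts (fractions). Values follow the ClinGen
  # gene-specific specifications for the HBOC genes; profiles/ carries
  # an alternative calibration.
  ba1_af: 1.0e-03
  bs1_af: 1.0e-04
  pm2_af: 1.0e-05
  # SpliceAI maximum delta score cuts.
  spliceai_pathogenic: 0.2
  spliceai_benign: 0.1
  # Minimum observation count in the cancer-free aged-women resource
  # (FLOSSIES) for BS2.
  bs2_count_min: 10
  # Pathogenicity-predictor strength cuts, pathogenic direction
  # (applied at the strongest strength whose cut the score reaches,
  # score >= cut). Calibrated-evidence interval estimates.
  patho_tool_cuts:
    revel:
      supporting: 0.644
      moderate: 0.773
      strong: 0.932
    bayesdel:
      supporting: 0.13
      moderate: 0.27
      strong: 0.50
  # Benign direction (score <= cut).
  patho_tool_benign_cuts:
    revel:
      supporting: 0.290
      moderate: 0.183
      strong: 0.016
    bayesdel:
      supporting: -0.18
      moderate: -0.36
  # Cosegregation likelihood-ratio cuts (Bayes factors per strength).
  pp1_lr_cuts:
    supporting: 2.08
    moderate: 4.33
    strong: 18.7
    very_strong: 350
  bs4_lr_cuts:
    supporting: 0.48
    moderate: 0.23
    strong: 0.053
  # Fallback cosegregation evidence when only a count of informative
  # meioses is available.
  pp1_meioses_cuts:
    supporting: 3
    moderate: 5
    strong: 7

rule_defaults:
  # PM2 downgraded from moderate to supporting per current guidance.
  pm2_strength: supporting
  bs2_strength: strong
  ps1_splicing_strength: moderate
  spliceai_pp3_strength: supporting
  spliceai_bp4_strength: supporting
  # BP7 may also apply to intronic variants outside the canonical
  # +/-1/2 positions.
  bp7_intronic_allowed: true
  # Downgrade start-loss PVS1 to supporting when an alternative
  # in-frame start is annotated for the transcript set.
  start_lost_alternative_start: false
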
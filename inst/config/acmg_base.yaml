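# Base ACMG/AMP scheme: used for genes without a gene-specific scheme
# (e.g. CHEK2, MSH2, RAD51D, PMS2, BRIP1).
scheme_id: acmg_base
version_label: acmg_amp_2015
gene: null
pathogenicity_tool: revel
splicing_tool: spliceai
bs2_allowed: true
# Functional-assay criteria (PS3/BS3) are automated only where curated
# assay data is available (BRCA1/BRCA2).
functional_rules_allowed: false
bp3_applicable: true
missense_constrained: false
truncating_mechanism: false
rna_integration: false
enabled_rules: [PVS1, PS1, PS3, PM1, PM2, PM4, PM5, PP1, PP2, PP3,
                BA1, BS1, BS2, BS3, BS4, BP1, BP3, BP4, BP7]
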
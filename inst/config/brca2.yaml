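scheme_id: brca2
version_label: v1.1.0
gene: BRCA2
pathogenicity_tool: bayesdel
splicing_tool: spliceai
bs2_allowed: false
functional_rules_allowed: true
bp3_applicable: false
missense_constrained: false
truncating_mechanism: true
rna_integration: true
enabled_rules: [PVS1, PS1, PS3, PM1, PM2, PM4, PM5, PP1, PP2, PP3,
                BA1, BS1, BS2, BS3, BS4, BP1, BP3, BP4, BP7]
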
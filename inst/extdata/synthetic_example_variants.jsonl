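{"variant":{"chrom":"17","pos":43093700,"ref":"TG","alt":"T","gene":"BRCA1","transcript":"NM_007294.4"},"tx":{"consequence":"frameshift","hgvs_c":"c.1175del","exon_index":10,"total_exons":23,"ptc_position":410,"last_junction_offset":-3200,"protein_length":1863,"is_last_exon":false},"pop":{"allele_count":0,"coverage_ok":true},"scores":{"spliceai_max_delta":0.02},"prior":{"same_aa_change":false,"same_codon_other_aa":false,"same_splice_site_pathogenic":false,"hotspot_overlap":false,"domain_overlap":false,"repeat_region":false},"assay":{"status":"absent","assay_strength":"strong"},"coseg":{},"rna":{"status":"absent"}}
{"variant":{"chrom":"17","pos":7675088,"ref":"C","alt":"T","gene":"TP53","transcript":"NM_000546.6"},"tx":{"consequence":"missense","hgvs_c":"c.524G>A","hgvs_p":"p.Arg175His","exon_index":5,"total_exons":11,"is_last_exon":false},"pop":{"popmax_af":1e-06,"allele_count":1,"coverage_ok":true},"scores":{"bayesdel":0.6,"spliceai_max_delta":0},"prior":{"same_aa_change":false,"same_codon_other_aa":false,"same_splice_site_pathogenic":false,"hotspot_overlap":true,"domain_overlap":true,"repeat_region":false},"assay":{"status":"absent","assay_strength":"strong"},"coseg":{},"rna":{"status":"absent"}}
{"variant":{"chrom":"16","pos":68801000,"ref":"C","alt":"T","gene":"CDH1","transcript":"NM_004360.5"},"tx":{"consequence":"synonymous","hgvs_c":"c.2076C>T","exon_index":13,"total_exons":16,"is_last_exon":false},"pop":{"popmax_af":0.0003,"allele_count":42,"coverage_ok":true,"flossies_count":14},"scores":{"revel":0.05,"spliceai_max_delta":0.01},"prior":{"same_aa_change":false,"same_codon_other_aa":false,"same_splice_site_pathogenic":false,"hotspot_overlap":false,"domain_overlap":false,"repeat_region":false},"assay":{"status":"absent","assay_strength":"strong"},"coseg":{},"rna":{"status":"absent"}}
{"variant":{"chrom":"22","pos":28695868,"ref":"A","alt":"G","gene":"CHEK2","transcript":"NM_007194.4"},"tx":{"consequence":"missense","hgvs_c":"c.1312T>C","exon_index":12,"total_exons":15,"is_last_exon":false},"pop":{"popmax_af":0.004,"allele_count":812,"coverage_ok":true},"scores":{"revel":0.2,"spliceai_max_delta":0.03},"prior":{"same_aa_change":false,"same_codon_other_aa":false,"same_splice_site_pathogenic":false,"hotspot_overlap":false,"domain_overlap":false,"repeat_region":false},"assay":{"status":"absent","assay_strength":"strong"},"coseg":{},"rna":{"status":"absent"}}
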
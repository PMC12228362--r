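{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "annotated_variant.schema.json",
  "title": "AnnotatedVariant",
  "description": "One pre-annotated small variant (<= 15 bp after left normalization) with all machine-readable evidence the classification criteria consume. Records travel as JSON Lines (one object per line) or a JSON array. Unknown fields are preserved as a passthrough bag.",
  "type": "object",
  "required": ["variant", "tx"],
  "properties": {
    "variant": {
      "type": "object",
      "required": ["chrom", "pos", "ref", "alt"],
      "properties": {
        "chrom": {"type": "string", "pattern": "^(chr)?([1-9]|1[0-9]|2[0-2]|X|Y|MT)$"},
        "pos": {"type": "integer", "minimum": 1},
        "ref": {"type": "string", "pattern": "^[ACGT]+$"},
        "alt": {"type": "string", "pattern": "^[ACGT]+$"},
        "gene": {"type": ["string", "null"]},
        "transcript": {"type": ["string", "null"]}
      }
    },
    "tx": {
      "type": "object",
      "required": ["consequence"],
      "properties": {
        "consequence": {"enum": ["missense", "synonymous", "nonsense", "frameshift", "inframe_indel", "splice_donor", "splice_acceptor", "intronic", "start_lost", "stop_lost", "UTR"]},
        "hgvs_c": {"type": ["string", "null"]},
        "hgvs_p": {"type": ["string", "null"]},
        "exon_index": {"type": ["integer", "null"], "minimum": 1},
        "total_exons": {"type": ["integer", "null"], "minimum": 1},
        "ptc_position": {"type": ["integer", "null"], "minimum": 1},
        "last_junction_offset": {"type": ["integer", "null"]},
        "protein_length": {"type": ["integer", "null"], "minimum": 1},
        "is_last_exon": {"type": "boolean"},
        "dist_to_splice_site": {"type": ["integer", "null"]},
        "splice_frame_disrupting": {"type": ["boolean", "null"]},
        "splice_nmd": {"type": ["boolean", "null"]}
      }
    },
    "pop": {
      "type": "object",
      "properties": {
        "popmax_af": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "allele_count": {"type": "integer", "minimum": 0},
        "coverage_ok": {"type": "boolean"},
        "flossies_count": {"type": ["integer", "null"], "minimum": 0}
      }
    },
    "scores": {
      "type": "object",
      "properties": {
        "revel": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "bayesdel": {"type": ["number", "null"]},
        "spliceai_max_delta": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "spliceai_event": {"enum": ["donor_loss", "donor_gain", "acceptor_loss", "acceptor_gain", null]}
      }
    },
    "prior": {
      "type": "object",
      "properties": {
        "same_aa_change": {"type": "boolean"},
        "same_codon_other_aa": {"type": "boolean"},
        "same_splice_site_pathogenic": {"type": "boolean"},
        "hotspot_overlap": {"type": "boolean"},
        "domain_overlap": {"type": "boolean"},
        "repeat_region": {"type": "boolean"}
      }
    },
    "assay": {
      "type": "object",
      "properties": {
        "status": {"enum": ["functional", "non_functional", "intermediate", "absent"]},
        "assay_strength": {"enum": ["strong", "moderate", "supporting"]}
      }
    },
    "coseg": {
      "type": "object",
      "properties": {
        "likelihood_ratio": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "informative_meioses": {"type": ["integer", "null"], "minimum": 0}
      }
    },
    "rna": {
      "type": "object",
      "properties": {
        "status": {"enum": ["absent", "confirmed_aberrant", "confirmed_normal_splicing"]}
      }
    }
  }
}
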
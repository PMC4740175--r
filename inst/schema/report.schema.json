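{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cphcap discovery report bundle",
  "type": "object",
  "required": ["version", "seed", "parameters", "qc"],
  "properties": {
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "parameters": {
      "type": "object",
      "required": ["fdr", "permutation_B", "mc_B", "panel_k"],
      "properties": {
        "fdr": {"type": "number"},
        "permutation_B": {"type": "number"},
        "mc_B": {"type": "number"},
        "mc_beta_min": {"type": "number"},
        "panel_k": {"type": "number"},
        "panel_top": {"type": "number"},
        "k_clusters": {"type": "number"}
      }
    },
    "qc": {
      "type": "object",
      "required": ["n_excluded_probes", "n_flagged_extracts", "mean_efficiency"],
      "properties": {
        "n_excluded_probes": {"type": "integer"},
        "n_flagged_extracts": {"type": "integer"},
        "mean_efficiency": {"type": "number"}
      }
    },
    "mvp": {"type": ["object", "null"]},
    "delta": {"type": ["object", "null"]},
    "resampling": {"type": ["object", "null"]},
    "classifier": {"type": ["object", "null"]},
    "clustering": {"type": ["object", "null"]},
    "corridor": {"type": ["object", "null"]},
    "replication": {"type": ["object", "null"]}
  }
}
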
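{
  "type": "object",
  "required": ["package", "mode", "master_seed", "stage_seeds", "parameters", "k", "stages_completed"],
  "properties": {
    "package": {"type": "string"},
    "config_hash": {"type": "number"},
    "mode": {"type": "string"},
    "master_seed": {"type": "integer"},
    "stage_seeds": {
      "type": "object",
      "required": ["simulate", "kselect", "embed", "kmeans", "stability", "cox"],
      "properties": {
        "simulate": {"type": "integer"},
        "kselect": {"type": "integer"},
        "embed": {"type": "integer"},
        "kmeans": {"type": "integer"},
        "stability": {"type": "integer"},
        "cox": {"type": "integer"}
      }
    },
    "parameters": {
      "type": "object",
      "required": ["embed_method", "k_range", "B_boot", "tau", "R_stab", "time_unit"],
      "properties": {
        "embed_method": {"type": "string"},
        "B_boot": {"type": "integer"},
        "tau": {"type": "number"},
        "R_stab": {"type": "integer"},
        "time_unit": {"type": "string"},
        "log_base": {"type": "string"}
      }
    },
    "k": {"type": "integer"},
    "stages_completed": {"type": "array"}
  }
}
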
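{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dualmem analysis report",
  "type": "object",
  "required": ["provenance", "groups", "fit", "curves", "stats",
               "efficacy_reduction", "range_fraction"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "input", "input_hash", "seed",
                   "model", "created"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "input": {"type": "string"},
        "input_hash": {"type": "string"},
        "seed": {"type": "integer"},
        "model": {"type": "string"},
        "created": {"type": "string"}
      }
    },
    "groups": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["n", "pc_r", "pc_t", "pc_t_pred", "te", "te_pred"],
        "properties": {
          "n": {"type": "integer"},
          "pc_r": {"type": "number"},
          "pc_t": {"type": "number"},
          "pc_t_pred": {"type": "number"},
          "pc_t_pred_fit": {"type": "number"},
          "te": {"type": "number"},
          "te_pred": {"type": "number"}
        }
      }
    },
    "fit": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["rho_hat", "converged", "boundary", "n"],
        "properties": {
          "rho_hat": {"type": "number"},
          "converged": {"type": "boolean"},
          "boundary": {"type": "string"},
          "n": {"type": "integer"}
        }
      }
    },
    "curves": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["independent", "correlated"],
        "properties": {
          "independent": {
            "type": "object",
            "required": ["mean_signed_dev", "mean_abs_dev", "max_abs_dev"],
            "properties": {
              "mean_signed_dev": {"type": "number"},
              "mean_abs_dev": {"type": "number"},
              "max_abs_dev": {"type": "number"}
            }
          },
          "correlated": {
            "type": "object",
            "required": ["mean_signed_dev", "mean_abs_dev", "max_abs_dev"]
          }
        }
      }
    },
    "stats": {
      "type": "object",
      "required": ["t_data_type", "note"],
      "properties": {
        "note": {"type": "string"}
      }
    },
    "efficacy_reduction": {"type": "object"},
    "range_fraction": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["lo", "hi", "closed", "open"],
        "properties": {
          "lo": {"type": "number"},
          "hi": {"type": "number"},
          "closed": {"type": "number"},
          "open": {"type": "number"}
        }
      }
    }
  }
}
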
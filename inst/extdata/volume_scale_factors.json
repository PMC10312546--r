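{
  "factors": { "H": 1.0, "C": 1.0, "N": 1.0, "O": 1.0 },
  "provenance": "identity defaults (uncalibrated); run calibrate_scale_factors() against a benchmark SWAXS profile with its fitted atomic model to obtain corrected factors and pass them via scale_factors= or this file"
}
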
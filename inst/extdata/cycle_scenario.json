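{
  "context": {"volume_fl": 1.32},
  "core": {"total": 11400},
  "species": [
    {"name": "sigma70", "total": 7600, "kd_core": 1e-9},
    {"name": "sigmaAlt", "total": 7600, "kd_core": 1e-9}
  ],
  "promoters": [
    {"name": "P70", "cognate_sigma": "sigma70", "count": 200, "km": 1e-9,
     "operon_length": 2000, "retention_length": 300,
     "release_mode": "separate_release"},
    {"name": "PAlt", "cognate_sigma": "sigmaAlt", "count": 200, "km": 1e-9,
     "operon_length": 2000, "retention_length": 300,
     "release_mode": "separate_release"}
  ],
  "level": "cycle",
  "seed": 1
}
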
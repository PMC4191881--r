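{
  "context": {"volume_fl": 1.32},
  "core": {"total": 11400, "kd_ns_core": 1e-4},
  "species": [
    {"name": "sigma70", "total": 5700, "kd_core": 1e-9},
    {"name": "sigmaAlt", "total": 8000, "kd_core": 1e-9}
  ],
  "level": "free",
  "scan": {"control": "sigmaAlt", "from": 100, "to": 20000, "n": 50},
  "onset": {"control": "sigmaAlt", "reference_value": 0, "observe": "sigma70"},
  "seed": 1
}
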
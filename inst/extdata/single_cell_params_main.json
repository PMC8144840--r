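{
  "transcription_rate_max": 3.5,
  "translation_rate": 10,
  "mrna_degradation": 0.023104906018664842,
  "protein_degradation": 0.007701635339554948,
  "autorepression_threshold": 25000,
  "autorepression_hill": 6,
  "transcription_delay_tau_h": 10,
  "noise_enabled": true,
  "_comment": "Single-cell HES5 parameter set used by default. Degradation rates are log(2)/30 and log(2)/90 per min (30-min mRNA and 90-min protein half-lives); the remaining values are calibrated so the uncoupled stochastic model shows a ~3.3 h ultradian period, a mean abundance of several tens of thousands of protein molecules, and tissue-like synchrony when coupled at the default inter-cellular parameters (tau_ND = 150 min, n = 4)."
}
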
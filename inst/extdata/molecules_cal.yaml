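# Voltage-gated Ca2+ channel as a one-site molecule (gating handled by the
# channel module; this declaration exists for the rule-dialect fixture).
molecules:
  CaL:
    diffusion: 0
    mobile: false
    sites: {gate: flag}
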
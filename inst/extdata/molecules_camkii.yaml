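# Molecule and site declarations of the Ca2+/CaM/CaMKII family.
# diffusion in cm^2/s; CaMKII subunits are immobilized.
molecules:
  ca:
    diffusion: 2.2e-6
    sites: {b: binding}
  cam:
    diffusion: 1.0e-7
    sites: {N1: binding, N2: binding, C1: binding, C2: binding, k: binding}
  K:
    diffusion: 0
    mobile: false
    sites: {cam: binding, p: flag}
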
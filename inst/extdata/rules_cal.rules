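# stochastic channel gating as a first-order flag rule
CaL{gate==0} <-> CaL{gate=1} kf=ro kb=rc label=CaL~gate
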
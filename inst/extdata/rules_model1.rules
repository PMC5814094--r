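# Ca2+ binding to free CaM: sequential within each lobe
cam{N1==0,N2==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1 label=N1~ca
cam{N1==1,N2==0} + ca{} <-> cam~ca{cam.N2=1} kf=kon_N2 kb=koff_N2 label=N2~ca
cam{C1==0,C2==0} + ca{} <-> cam~ca{cam.C1=1} kf=kon_C1 kb=koff_C1 label=C1~ca
cam{C1==1,C2==0} + ca{} <-> cam~ca{cam.C2=1} kf=kon_C2 kb=koff_C2 label=C2~ca
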
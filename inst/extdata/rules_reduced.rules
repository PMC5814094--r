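# reduced network: C-lobe loading, one N step, subunit binding, phosphorylation
cam{N1==0,N2==0,C1==0,C2==0,k==0} + ca{} <-> cam~ca{cam.C1=1} kf=kon_C1 kb=koff_C1 label=C1~ca@N0C0
cam{N1==0,N2==0,C1==1,C2==0,k==0} + ca{} <-> cam~ca{cam.C2=1} kf=kon_C2 kb=koff_C2 label=C2~ca@N0C1
cam{N1==0,N2==0,C1==1,C2==1,k==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1 label=N1~ca@N0C2
cam{N1==0,N2==0,C1==1,C2==1} + K{p==0} <-> cam~K{cam.k=1} kf=kon_cam_K kb=koff_cam_K_0_2 label=K~N0C2
cam{N1==1,N2==0,C1==1,C2==1} + K{p==0} <-> cam~K{cam.k=1} kf=kon_cam_K kb=koff_cam_K_1_2 label=K~N1C2
cam{N1==0,N2==0,C1==1,C2==1,k==1,partner(k).p==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1_K label=KN1~ca@KN0C2
K{p==0,cam==1,partner(cam).N1==1,partner(cam).N2==0,partner(cam).C1==1,partner(cam).C2==1} -> K{p=1} kf=kp_reduced label=KN1C2~p
ca{b==0} -> 0 kf=k_clear label=ca~clear
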
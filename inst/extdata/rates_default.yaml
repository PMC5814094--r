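# Default kinetic constants for the Ca2+/CaM/CaMKII network.
#
# These are literature-informed defaults (fast low-affinity N lobe, slow
# high-affinity C lobe, cooperative second site within each lobe), and are
# assumptions: the network's context-dependent constants are derived from
# them by thermodynamic linkage (see default_rates()), which makes the full
# network satisfy microscopic reversibility by construction. Replace any
# value here to drop in a measured parameter table.
#
# units: kon uM^-1 s^-1; koff s^-1; Kd uM; phosphorylation rates s^-1

# Ca2+ binding to free CaM
kon_N1: 100
koff_N1: 1000      # Kd 10 uM
kon_N2: 150
koff_N2: 750       # Kd 5 uM (cooperative)
kon_C1: 5
koff_C1: 10        # Kd 2 uM
kon_C2: 10
koff_C2: 10        # Kd 1 uM (cooperative)

# per-site Ca2+ affinity gain when CaM is bound to a subunit / to a
# phosphorylated subunit (trapping emerges from g_Kp via linkage)
g_K: 5
g_Kp: 25

# CaM binding to CaMKII subunits (apoCaM reference affinity; state-dependent
# koff follows Kd0 / g^(x+y))
kon_cam_K: 20
Kd0_cam_K: 100
kon_cam_Kp: 20
Kd0_cam_Kp: 100

# autophosphorylation rate by bound-CaM state (symmetric in the two lobes so
# the restricted schemes use matched rates)
kp_00: 0.02
kp_10: 0.1
kp_01: 0.1
kp_11: 0.3
kp_20: 0.5
kp_02: 0.5
kp_21: 1.0
kp_12: 1.0
kp_22: 3.0
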
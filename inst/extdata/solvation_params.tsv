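# source: Eisenberg & McLachlan (1986) atomic solvation parameters
#   (C +16, S +21, neutral N/O -6, charged O -24, charged N -50
#   cal mol^-1 A^-2), converted to kcal mol^-1 A^-2; united-atom
#   heavy-atom radii in the Chothia (1976) convention.
# probe_radius: 1.4
atom_class	asp_kcal_per_A2	radius_A
C_aliphatic	0.016	1.87
C_aromatic	0.016	1.76
C_carbonyl	0.016	1.76
N_polar	-0.006	1.65
N_charged	-0.050	1.65
O_polar	-0.006	1.40
O_charged	-0.024	1.40
S	0.021	1.85
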
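label	n_aa	folded_distance_nm	theoretical_dlc_nm
alpha(Cys34-Cys67)	34	1.3	10.94
beta(Cys6-Cys30)	25	1.2	7.8
alpha(Cys34-Cys45)	12	0.72	3.6
alpha(Cys45-Cys67)	22	0.42	7.5
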
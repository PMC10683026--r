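condition	cv1_force_constant	cv2_force_constant	cv1_diffusion	cv2_diffusion
apo	10000	10000	0.001	0.001
adrenaline	10000	10000	0.0005	0.0005
alprenolol	10000	10000	0.001	0.001
BI-167107	10000	10000	0.005	0.005
carazolol	10000	10000	0.001	0.001
formoterol	10000	10000	0.001	0.001
mirabegron	10000	10000	0.0005	0.0005
salbutamol	10000	10000	0.001	0.001
salmeterol	10000	10000	0.001	0.001
timolol	10000	10000	0.001	0.001
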
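# Atomic van der Waals radii in nm (Bondi-type consensus values).
# The set is deliberately swappable: pass a custom file to vdw_radius_table().
element	radius_nm
H	0.120
C	0.170
N	0.155
O	0.152
F	0.147
P	0.180
S	0.180
Cl	0.175
Br	0.185
I	0.198
B	0.192
Na	0.227
Mg	0.173
K	0.275
Ca	0.231
Mn	0.205
Fe	0.205
Co	0.200
Ni	0.163
Cu	0.140
Zn	0.139
Se	0.190
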
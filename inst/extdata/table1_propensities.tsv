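residue	odds_prion_domain	lor_prion_domain	odds_library1	lor_library1
A	0.675	-0.568	0.670	-0.578
C	0.071	-3.807	1.520	0.604
D	0.352	-1.507	0.280	-1.837
E	0.147	-2.766	0.550	-0.862
F	0.718	-0.478	2.310	1.208
G	1.028	0.040	0.960	-0.059
H	0.913	-0.131	0.760	-0.396
I	0.350	-1.515	2.260	1.176
K	0.271	-1.883	0.210	-2.252
L	0.340	-1.556	0.960	-0.059
M	1.125	0.170	1.960	0.971
N	5.700	2.511	1.080	0.111
P	1.170	0.227	0.300	-1.737
Q	4.125	2.044	1.070	0.098
R	0.436	-1.196	0.670	-0.578
S	1.662	0.733	1.140	0.189
T	0.830	-0.268	0.890	-0.168
V	0.304	-1.716	2.260	1.176
W	0.091	-3.459	1.950	0.963
Y	1.724	0.786	2.180	1.124
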
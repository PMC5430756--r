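node	age_my	provenance
OUT2	390	interpolated
OUT1	350	interpolated
ISO	307	printed
ONI	117	printed
N66	66	printed
NB	56.667	interpolated
PHI	36	printed
PO	15	printed
NC	47.333	interpolated
ARM	36.167	interpolated
A25	25	printed
a1	20.833	interpolated
a2	16.667	interpolated
a3	12.5	interpolated
a4	8.333	interpolated
a5	4.167	interpolated
a6	9.375	interpolated
a7	6.25	interpolated
a8	3.125	interpolated
TRA	38	printed
PORF	36.5	interpolated
POR	35	printed
p1	26.25	interpolated
p2	17.5	interpolated
p3	8.75	interpolated
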
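# One-bead-per-residue force-field table, HPS (hydropathy scale) family.
# code: 1-letter residue code ('p' = phospho-serine)
# mass: amu; sigma: van der Waals diameter, nm; lambda: hydropathy (0..1);
# charge: elementary charges.
# source: KR = Kapcha-Rossky hydropathy scale as normalized for the HPS model;
#         package default (pSer row: phospho-residue extension defaults,
#         overridable).
code	mass	sigma	lambda	charge	source
A	71.08	0.504	0.730	0	KR
R	156.2	0.656	0.000	1	KR
N	114.1	0.568	0.432	0	KR
D	115.1	0.558	0.378	-1	KR
C	103.1	0.548	0.595	0	KR
Q	128.1	0.602	0.514	0	KR
E	129.1	0.592	0.459	-1	KR
G	57.05	0.450	0.649	0	KR
H	137.1	0.608	0.514	0	KR
I	113.2	0.618	0.973	0	KR
L	113.2	0.618	0.973	0	KR
K	128.2	0.636	0.514	1	KR
M	131.2	0.618	0.838	0	KR
F	147.2	0.636	1.000	0	KR
P	97.12	0.556	1.000	0	KR
S	87.08	0.518	0.595	0	KR
T	101.1	0.562	0.676	0	KR
W	186.2	0.678	0.946	0	KR
Y	163.2	0.646	0.865	0	KR
V	99.07	0.586	0.892	0	KR
p	167.05	0.636	0.400	-2	package default
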
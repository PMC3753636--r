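# Synthetic dinucleotide stiffness table (stand-in parameter set).
# Diagonal force constants for the six helical deformation channels:
# twist/tilt/roll in kcal/(mol.deg^2), shift/slide/rise in kcal/(mol.A^2).
# Values are randomly drawn at physically plausible magnitudes and are NOT
# a published molecular-dynamics-derived set; swap in a real table with
# load_stiffness_table().
step	twist	tilt	roll	shift	slide	rise
AA	0.05247	0.05607	0.04800	2.55048	2.45922	2.86077
CA	0.02003	0.04888	0.01984	2.71240	1.88679	1.97259
GA	0.04901	0.01822	0.02076	2.62151	2.76174	2.81241
TA	0.05128	0.05920	0.01278	2.56356	1.28114	0.51264
AC	0.04755	0.04231	0.05932	1.04781	2.77683	1.25583
CC	0.02296	0.04772	0.02981	1.60849	1.22488	2.91450
GC	0.03778	0.02340	0.04615	2.68446	2.17864	1.74360
TC	0.04901	0.01822	0.02076	2.62151	2.76174	2.81241
AG	0.02432	0.05858	0.01093	1.57282	1.41789	1.11162
CG	0.01962	0.01186	0.03530	2.77506	1.16994	0.84622
GG	0.02296	0.04772	0.02981	1.60849	1.22488	2.91450
TG	0.02003	0.04888	0.01984	2.71240	1.88679	1.97259
AT	0.04797	0.04684	0.05545	2.65573	2.23222	2.33551
CT	0.02432	0.05858	0.01093	1.57282	1.41789	1.11162
GT	0.04755	0.04231	0.05932	1.04781	2.77683	1.25583
TT	0.05247	0.05607	0.04800	2.55048	2.45922	2.86077
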
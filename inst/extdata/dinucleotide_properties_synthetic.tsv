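oligo	P1	P2	P3	P4	P5	P6
AA	-0.833	-0.822	-0.961	0.101	-0.011	0.751
AC	-1.817	-0.354	0.041	-0.787	0.26	-1.319
AG	-0.167	-0.531	-0.709	-1.015	0.625	1.038
AT	0.179	-0.086	0.979	0.38	0.579	-0.395
CA	1.029	-0.595	-1.433	0.319	0.282	0.593
CC	0.61	1.901	-0.504	1.196	-0.204	-0.764
CG	0.883	0.287	-0.131	-0.529	-0.583	-0.323
CT	0.945	0.259	-0.34	0.951	-0.648	-0.458
GA	0.421	-0.254	0.769	0.806	1.172	-0.346
GC	-1.433	1.953	-1.755	-0.432	1.252	0.966
GG	0.32	0.574	-1.054	-1.454	0.242	1.557
GT	0.414	0.185	1.279	-1.245	-1.94	1.378
TA	0.446	-0.993	-0.81	0.039	0.833	-0.406
TC	-0.377	-1.289	-1.52	1.096	-0.006	1.95
TG	0.72	0.073	0.235	-0.283	0.083	0.319
TT	-0.48	-0.808	0.49	0.834	-0.32	0.636
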
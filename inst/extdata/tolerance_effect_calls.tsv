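gene	cluster	allele_class	etoh	ba
Ack-like	1	Tub-Gal4 RNAi	-	-
trr	1	elav-Gal4 RNAi	-	-
msn	1	elav-Gal4 RNAi	-	+
pum	1	loss of function/hypomorphic	+	+
nej	1	loss of function/heterozygous null	+	+
unc-104	2	elav-Gal4 RNAi	-	-
nAcRalpha-30D	4	loss of function/null	-	-
eag	4	loss of function/hypomorphic	+	+
Teh2	4	Tub-Gal4 RNAi	+	+
slo	4	loss of function/null	+	+
Ptp99A	4	Tub-Gal4 RNAi	+	+
mam	4	elav-Gal4 RNAi	+	+
brp	4	elav-Gal4 RNAi	+	+
Ten-a	4	Tub-Gal4 RNAi	+	+
Dscam	4	elav-Gal4 RNAi	-	-
kn	4	Tub-Gal4 RNAi	+	+
para	4	elav-Gal4 RNAi	L	L
so	5	loss of function	-	-
Act57B	7	Tub-Gal4 RNAi	-	-
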
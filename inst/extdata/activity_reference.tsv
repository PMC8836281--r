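flavour	sequence	activity	count	A	B
db	LDTANEMNQLDLQFR	ACE inhibitor	3	0.2000	7.24e-5
db	LDTANEMNQLDLQFR	DPP IV inhibitor	7	0.4667
db	LDTANEMNQLDLQFR	DPP III inhibitor	1	0.0667
db	LDTANEMNQLDLQFR	Renin inhibitor	1	0.0667
db	VVLQDTSNNVNQLD	ACE inhibitor	2	0.1429
db	VVLQDTSNNVNQLD	Glucose uptake stimulation	1	0.0714
db	VVLQDTSNNVNQLD	DPP IV inhibitor	9	0.6429	9.65e-4
db	VVLQDTSNNVNQLDDIPRRFFLA	ACE inhibitor	9	0.3913	1.36e-2
db	VVLQDTSNNVNQLDDIPRRFFLA	Activator of ubiquitin-mediated proteolysis	1	0.0435
db	VVLQDTSNNVNQLDDIPRRFFLA	DPP IV inhibitor	10	0.2174
db	VVLQDTSNNVNQLDDIPRRFFLA	DPP III inhibitor	5	0.6087	8.62e-4
db	VVLQDTSNNVNQLDDIPRRFFLA	Stimulation	1	0.0435
db	AVVPIWLQPDTPAR	ACE inhibitor	10	0.7143	5.69e-2
db	AVVPIWLQPDTPAR	DPP IV inhibitor	10	0.7143	1.80e-3
db	IFSGGESSGQPR	ACE inhibitor	9	0.7500	4.63e-2
db	IFSGGESSGQPR	Antioxidant	1	0.0833
db	IFSGGESSGQPR	DPP III inhibitor	2	0.1667
db	IFSGGESSGQPR	DPP IV inhibitor	4	0.3333
db	IFSGGESSGQPR	Neuropeptide	1	0.0833
db	DTSNNVNQLDDIPRR	ACE inhibitor	3	0.2000	1.70e-2
db	DTSNNVNQLDDIPRR	DPP IV inhibitor	8	0.1333
db	DTSNNVNQLDDIPRR	DPP III inhibitor	2	0.5333	1.62e-4
db	NCSTSIISG	ACE inhibitor	2	0.2222	2.75e-2
db	NCSTSIISG	DPP IV inhibitor	3	0.3333
db	NCSTSIISG	Glucose uptake stimulation	1	0.1111
db	VHVFRFDQNQDLLPIGN	ACE inhibitor	5	0.2941	8.20e-3
db	VHVFRFDQNQDLLPIGN	Glucose uptake stimulation	1	0.0588
db	VHVFRFDQNQDLLPIGN	DPP IV inhibitor	11	0.6471	2.48e-5
db	VHVFRFDQNQDLLPIGN	DPP III inhibitor	2	0.1176
db	LLLGAGCM(+15.99)	ACE inhibitor	3	0.3750	1.26e-4
db	LLLGAGCM(+15.99)	Glucose uptake stimulation	2
db	LLLGAGCM(+15.99)	Stimulation of vasoactive substance release	1	0.3750
db	LLLGAGCM(+15.99)	DPP IV inhibitor	3	0.5000
db	QDTSNNVNQLDDIPRR	ACE inhibitor	3	0.1875	1.59e-2
db	QDTSNNVNQLDDIPRR	DPP IV inhibitor	9	0.5625	1.52e-4
db	QDTSNNVNQLDDIPRR	DPP III inhibitor	2	0.1250
db	FSASTEGS	ACE inhibitor	4	0.5000	3.11e-2
db	FSASTEGS	DPP IV inhibitor	3	0.3750
db	INTISGR	ACE inhibitor	2	0.2857	6.14e-5
db	INTISGR	DPP IV inhibitor	3	0.4286
db	LDGNSSAR	ACE inhibitor	2	0.2500	1.14e-2
db	VCGEAFGKA	ACE inhibitor	7	0.7778	4.80e-3
db	VCGEAFGKA	Alpha-glucosidase inhibitor	1	0.1111	6.53e-6
db	VCGEAFGKA	DPP IV inhibitor	3	0.3333	1.78e-5
db	VCGEAFGKA	DPP III inhibitor	2	0.2222
db	KGGGGGSGSAGGGGS	ACE inhibitor	13	0.8667	1.72e-4
db	KGGGGGSGSAGGGGS	DPP IV inhibitor	9	0.6000
db	SGPGNHEQ	ACE inhibitor	4	0.5000	2.10e-3
db	SGPGNHEQ	Antiamnestic	2	0.2500
db	SGPGNHEQ	Antithrombotic	2	0.2500
db	SGPGNHEQ	Regulation of stomach mucosal activity	2	0.2500
db	SGPGNHEQ	DPP IV inhibitor	4	0.5000	1.80e-3
db	LGGGGSSGGAAC	ACE inhibitor	9	0.7500	2.63e-4
db	LGGGGSSGGAAC	Antioxidant	1	0.0833
db	LGGGGSSGGAAC	DPP IV inhibitor	6	0.5000	8.87e-6
db	NALLCSNS	Glucose uptake stimulation	1	0.1250
db	NALLCSNS	DPP IV inhibitor	3	0.3750	1.42e-6
db	CPANGFY	ACE inhibitor	3	0.4286	5.90e-3
db	CPANGFY	DPP IV inhibitor	3	0.4286
db	CPANGFY	DPP III inhibitor	1	0.1429
denovo	CCYSVY	ACE inhibitor	2	0.3333	4.39e-2
denovo	CCYSVY	Antioxidant	1	0.1667
denovo	CCYSVY	DPP III inhibitor	3	0.1667
denovo	CCYSVY	DPP IV inhibitor	1	0.5000
denovo	DCHYFL	ACE inhibitor	1	0.1667	6.38e-3
denovo	DCHYFL	Anti-inflammatory	1	0.1667
denovo	DCHYFL	DPP III inhibitor	3	0.3333
denovo	DCHYFL	DPP IV inhibitor	2	0.5000	4.17e-4
denovo	LYPFAH	ACE inhibitor	4	0.6667	3.47e-4
denovo	LYPFAH	Alpha-glucosidase inhibitor	1	0.1667	9.92e-5
denovo	LYPFAH	Antioxidant	2	0.3333
denovo	LYPFAH	DPP III inhibitor	2	0.3333
denovo	LYPFAH	DPP IV inhibitor	4	0.6667	5.25e-5
denovo	LYPFAH	Opioid	1	0.1667
denovo	LYPFAH	Renin inhibitor	1	0.1667
denovo	SVSKPGW	ACE inhibitor	3	0.4286	1.12e-2
denovo	SVSKPGW	Antiamnestic	1	0.1429
denovo	SVSKPGW	Antioxidant	1	0.1429
denovo	SVSKPGW	Antithrombotic	1	0.1429
denovo	SVSKPGW	Regulation of stomach activity	1	0.1429
denovo	SVSKPGW	DPP IV inhibitor	6	0.8571	5.62e-5
denovo	LHTVVH	Antioxidant	2	0.3333
denovo	LHTVVH	DPP IV inhibitor	5	0.8333
denovo	NKLCCEH	ACE inhibitor	3	0.4286	4.64e-3
denovo	NKLCCEH	DPP IV inhibitor	1	0.1429
denovo	DHHEEL	Antioxidative	3	0.5000
denovo	DHHEEL	Stimulation of vasoactive substance release	1	0.1667
denovo	DHHEEL	DPP IV inhibitor	2	0.3333
denovo	LPCAAHR	ACE inhibitor	2	0.2857	2.30e-4
denovo	LPCAAHR	Antioxidant	1	0.1429
denovo	LPCAAHR	DPP IV inhibitor	4	0.5714	7.54e-5
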
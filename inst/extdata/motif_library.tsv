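fragment	activity	ec50_uM	source
VY	ACE_inhibitor	7.1	published IC50 7.1 uM
SVY	ACE_inhibitor	8.1	published IC50 8.1 uM
KA	ACE_inhibitor	31.5	published IC50 31.5 uM
FL	ACE_inhibitor	15.8	published IC50 15.8 uM
IPP	ACE_inhibitor	5	dairy lactotripeptide, IC50 5 uM
VPP	ACE_inhibitor	9	dairy lactotripeptide, IC50 9 uM
FY	ACE_inhibitor	22.125	published IC50 range 1.65-42.6 uM; midpoint stored
GF	ACE_inhibitor		activity annotation, no published IC50
QF	ACE_inhibitor		activity annotation, no published IC50
IF	ACE_inhibitor		activity annotation, no published IC50
RF	ACE_inhibitor		activity annotation, no published IC50
VVL	ACE_inhibitor		activity annotation, no published IC50
QF	renin_inhibitor		activity annotation, no published IC50
QF	DPP_IV_inhibitor		activity annotation, no published IC50
QL	DPP_IV_inhibitor		activity annotation, no published IC50
VN	DPP_IV_inhibitor		activity annotation, no published IC50
IN	DPP_IV_inhibitor		activity annotation, no published IC50
AL	DPP_IV_inhibitor		activity annotation, no published IC50
GF	DPP_IV_inhibitor		activity annotation, no published IC50
RF	DPP_III_inhibitor		activity annotation, no published IC50
GF	DPP_III_inhibitor		activity annotation, no published IC50
YPF	opioid		activity annotation, no published IC50
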
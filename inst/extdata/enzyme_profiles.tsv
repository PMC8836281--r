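name	p1	blockP1prime
pepsin_ph1.3	FL
trypsin	KR	P
chymotrypsin_like	FLMNWY	P
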
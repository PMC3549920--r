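label	x	y	z	radius_mm
leftAud	-45	-20	5	9
rightAud	45	-20	5	9
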
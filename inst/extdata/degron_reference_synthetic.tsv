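class	sequence
D_ext	RTALGDIGN
D_ext	RAALSEIGN
D_ext	RSPLADITN
D_ext	RQALGVVEN
D_ext	RTVLGEIGN
D_min	RTAL
D_min	RAAL
D_min	RSPL
D_min	RQAL
D_min	RTVL
KEN	KEN
KEN	KEN
KEN	KEN
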
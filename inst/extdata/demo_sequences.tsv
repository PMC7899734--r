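1	ABABABEBAEAEACACAEA
2	EAEAEAEABABCBC(D;G)C(D;G)
3	C(D;G)C(D;G)C(D;G)CEAEAEFEF
4	EFEFEFCFC(D;G)C(D;G)FC(D;G)
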
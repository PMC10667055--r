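M6A_REGULATORS	m6A writer/eraser/reader regulator genes as printed; see alias table	METTL3	METTL14	METTL16	WTAP	VIRMA	ZC3H13	RBM15	RBM15B	YTHDC1	YTHDC2	YTHDF1	YTHDF2	YTHDF3	HNRNPC	FMR1	L RPPRC	HNRNPA2B1	IGFBP1	IGFBP2	IGFBP3	RBMX	FTO	ALKBH
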
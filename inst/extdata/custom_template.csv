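PROTEIN_SEQUENCE,
PROTEIN_NAME,
PROTEIN_STATE,
"TEMPERATURE (K)",
pH(READ),
D2O_SATURATION,
START,END,SEQUENCE,MOD,REP,PTM_CONTENT,TIME(SEC),UPTAKE,ENVELOPE
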
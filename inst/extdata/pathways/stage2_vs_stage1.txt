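cytokine cytokine receptor interaction
hematopoietic cell lineage
mapk signaling pathway
long term depression
cell cycle
cell communication
prion disease
small cell lung cancer
focal adhesion
natural killer cell mediated cytotoxicity
colorectal cancer
ecm receptor interaction
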
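cell communication
ecm receptor interaction
focal adhesion
cytokine cytokine receptor interaction
arachidonic acid metabolism
metabolism of xenobiotics by cytochrome p450
bladder cancer
complement and coagulation cascades
colorectal cancer
hematopoietic cell lineage
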
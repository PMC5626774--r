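cell communication
ecm receptor interaction
focal adhesion
arachidonic acid metabolism
metabolism of xenobiotics by cytochrome p450
cytokine cytokine receptor interaction
bladder cancer
complement and coagulation cascades
cell cycle
urea cycle and metabolism of amino groups
tryptophan metabolism
colorectal cancer
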
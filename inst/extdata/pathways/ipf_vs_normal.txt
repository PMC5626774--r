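cell communication
ecm receptor interaction
focal adhesion
metabolism of xenobiotics by cytochrome p450
cytokine cytokine receptor interaction
complement and coagulation cascades
long term depression
calcium signaling pathway
urea cycle and metabolism of amino groups
colorectal cancer
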
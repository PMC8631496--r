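stimulus,activity,sign,significant,epsilon
glucose,IL1B_mRNA,activating,FALSE,
pH,IL1B_mRNA,activating,TRUE,81
glucose,TNFA_mRNA,activating,FALSE,
pH,TNFA_mRNA,activating,FALSE,
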
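stimulus,activity,sign,significant,epsilon
glucose,Agg,activating,FALSE,
glucose,ColI,activating,FALSE,
glucose,ColII,activating,FALSE,
glucose,MMP3,activating,FALSE,
glucose,ADAMTS4,activating,FALSE,
pH,Agg,activating,TRUE,0.37
pH,ColI,activating,FALSE,
pH,ColII,activating,TRUE,0.63
pH,MMP3,activating,TRUE,28.7
pH,ADAMTS4,activating,TRUE,5.7
IL1B,Agg,inhibiting,TRUE,0.45
IL1B,ColI,activating,FALSE,
IL1B,ColII,inhibiting,FALSE,
IL1B,MMP3,activating,TRUE,10.8
IL1B,ADAMTS4,inhibiting,FALSE,
TNFA,Agg,inhibiting,FALSE,
TNFA,ColI,inhibiting,TRUE,0.31
TNFA,ColII,inhibiting,TRUE,0.06
TNFA,MMP3,activating,TRUE,26.85
TNFA,ADAMTS4,activating,TRUE,5.77
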
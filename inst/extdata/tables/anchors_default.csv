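stimulus,activity,concentration,normalized_response
glucose,Agg,0,0
glucose,Agg,0.5,0.75
glucose,Agg,0.8,0.92
glucose,Agg,1,0.97
glucose,Agg,5,1
glucose,ColI,0,0
glucose,ColI,0.5,0.75
glucose,ColI,0.8,0.92
glucose,ColI,1,0.97
glucose,ColI,5,1
glucose,ColII,0,0
glucose,ColII,0.5,0.75
glucose,ColII,0.8,0.92
glucose,ColII,1,0.97
glucose,ColII,5,1
glucose,MMP3,0,0
glucose,MMP3,0.5,0.75
glucose,MMP3,0.8,0.92
glucose,MMP3,1,0.97
glucose,MMP3,5,1
glucose,ADAMTS4,0,0
glucose,ADAMTS4,0.5,0.75
glucose,ADAMTS4,0.8,0.92
glucose,ADAMTS4,1,0.97
glucose,ADAMTS4,5,1
glucose,IL1B_mRNA,0,0
glucose,IL1B_mRNA,0.5,0.75
glucose,IL1B_mRNA,0.8,0.92
glucose,IL1B_mRNA,1,0.97
glucose,IL1B_mRNA,5,1
glucose,TNFA_mRNA,0,0
glucose,TNFA_mRNA,0.5,0.75
glucose,TNFA_mRNA,0.8,0.92
glucose,TNFA_mRNA,1,0.97
glucose,TNFA_mRNA,5,1
pH,Agg,6.5,0
pH,Agg,6.8,0.25
pH,Agg,7.0,0.6
pH,Agg,7.2,0.9
pH,Agg,7.4,1
pH,ColI,6.5,0
pH,ColI,6.8,0.25
pH,ColI,7.0,0.6
pH,ColI,7.2,0.9
pH,ColI,7.4,1
pH,ColII,6.5,0
pH,ColII,6.8,0.25
pH,ColII,7.0,0.6
pH,ColII,7.2,0.9
pH,ColII,7.4,1
pH,MMP3,6.5,1
pH,MMP3,6.8,0.75
pH,MMP3,7.0,0.4
pH,MMP3,7.2,0.1
pH,MMP3,7.4,0
pH,ADAMTS4,6.5,1
pH,ADAMTS4,6.8,0.75
pH,ADAMTS4,7.0,0.4
pH,ADAMTS4,7.2,0.1
pH,ADAMTS4,7.4,0
pH,IL1B_mRNA,6.5,1
pH,IL1B_mRNA,6.8,0.75
pH,IL1B_mRNA,7.0,0.4
pH,IL1B_mRNA,7.2,0.1
pH,IL1B_mRNA,7.4,0
pH,TNFA_mRNA,6.5,1
pH,TNFA_mRNA,6.8,0.75
pH,TNFA_mRNA,7.0,0.4
pH,TNFA_mRNA,7.2,0.1
pH,TNFA_mRNA,7.4,0
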
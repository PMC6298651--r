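condition,effect,g150,g250,up,down
glucose,noncoding,4,9,2,1
glucose,missense,47,61,17,4
glucose,frameshift,4,5,1,1
glucose,synonymous,1,7,0,0
glucose,stop_gained,4,10,2,0
glucose,start_lost,0,1,0,0
glucose,splice,2,3,0,1
glucose,mito,0,0,0,0
glucose,inframe_insertion,0,0,0,0
urea,noncoding,8,12,1,0
urea,missense,22,34,6,2
urea,frameshift,5,6,2,0
urea,synonymous,4,10,2,0
urea,stop_gained,7,4,0,2
urea,start_lost,0,0,0,0
urea,splice,0,0,0,0
urea,mito,0,2,0,0
urea,inframe_insertion,0,0,0,0
glutamine,noncoding,6,5,0,0
glutamine,missense,12,22,4,1
glutamine,frameshift,2,2,0,0
glutamine,synonymous,4,3,0,0
glutamine,stop_gained,0,5,0,0
glutamine,start_lost,0,0,0,0
glutamine,splice,0,1,0,0
glutamine,mito,0,0,0,0
glutamine,inframe_insertion,0,1,0,0
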
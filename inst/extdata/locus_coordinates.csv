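name,chrom,start,end
reporter_integration,chrXI,513945,517320
target_gene_GAP1,chrXI,518438,520246
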
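# species: Toyus exampleus
# source: observed
index,rel_position,LA_um2,LRD_um,WT_um
1,0,820,30.8,2.8
2,0.25,700,26.5,3.0
3,0.5,560,21.0,3.2
4,0.75,430,16.0,3.4
5,1,373,12.3,3.6
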
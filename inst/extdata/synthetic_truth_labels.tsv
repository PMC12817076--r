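gene_id	outcome	prediction_ids
g00001	exact	p_g00001
g00002	fragmented	p_g00002_frag1,p_g00002_frag2
g00003	exact	p_g00003
g00004	missing	
g00005	merged	p_merged_0001
g00006	inexact	p_g00006
g00007	merged	p_merged_0001
g00008	inexact	p_g00008
g00009	missing	
g00010	exact	p_g00010
g00011	inexact	p_g00011
g00012	exact	p_g00012
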
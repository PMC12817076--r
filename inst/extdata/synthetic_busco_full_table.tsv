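# synthetic BUSCO-style full_table for the worked example
b001	Fragmented	g00001	171.8	186
b002	Complete	g00002	437.3	254
b003	Complete	g00003	279.7	366
b004	Complete	g00004	480.3	259
b005	Fragmented	g00005	338.8	378
b006	Complete	g00006	453.2	314
b007	Fragmented	g00007	595.8	183
b008	Fragmented	g00008	277.6	255
b009	Complete	g00009	484.3	275
b010	Complete	g00010	566	238
b011	Complete	g00011	190.3	321
b012	Complete	g00012	418.9	356
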
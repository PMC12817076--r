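# synthetic curated (Swiss-Prot-style) gene ids
g00001
g00003
g00005
g00007
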
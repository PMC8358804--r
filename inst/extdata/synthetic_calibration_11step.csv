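"gray","od"
16.089,1.2
21.21,1.08
27.96,0.96
36.859,0.84
48.589,0.72
64.053,0.6
84.438,0.48
111.312,0.36
146.737,0.24
193.437,0.12
255,0
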
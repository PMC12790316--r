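id,epsilon_homo
1,-0.137
37,-0.128
38,-0.129
48,-0.132
32,-0.130
41,-0.130
92,-0.137
39,-0.130
33,-0.133
73,-0.137
12,-0.153
11,-0.150
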
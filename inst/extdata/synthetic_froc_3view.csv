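fp_per_node;sensitivity_percent
0.25;55
0.5;62
1;68
2;74
4;80
8;85
16;89
32;92
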
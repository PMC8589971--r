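# 9-node illustration network
1 2
2 3
2 7
3 4
3 7
4 5
4 6
4 7
5 6
5 7
6 7
5 8
6 9
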
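# synthetic structure-based contact map: chain_id i j distance_A
1 3 12 6.4
1 5 17 6.9
2 10 31 6.1
2 14 40 7.2
6 4 18 6.5
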
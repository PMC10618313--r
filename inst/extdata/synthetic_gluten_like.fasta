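>gliadin_like_1 copies=3 synthetic Q/P/G-rich demo chain
QQPQQPFGQQAQQPGQGQQSQQPGQGQQCQQPAQLQQPGQGQQTQQPGQG
>glutenin_like_1 copies=2 synthetic high-molecular-weight demo chain
GQQPGQGQQGYYPTSPQQSGQGQQCGQGQQPGQGQPGYYPTSSQQSGQGQQGQQPGQGQC
>gliadin_like_2 synthetic short demo chain
QPQQPQQSFPQQQPVLPQQSPF
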
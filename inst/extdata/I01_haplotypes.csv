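id,M1
1,14
2,14
3,14
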
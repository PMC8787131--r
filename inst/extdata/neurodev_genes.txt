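Adcy1
Nr4a2
Six4
Stx16
Ube3a
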
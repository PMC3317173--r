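((((sp07|g1,sp10|g1),(sp11|g1,(sp02|g1,sp04|g1))),sp08|g1),((sp09|g1,sp09|g2),(((sp03|g1,(sp05|g1,sp05|g2)),sp01|g1),((sp12|g1,sp12|g2),sp06|g1))));
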
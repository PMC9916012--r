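quantity,men,women
input,10754,12515
analysis,10724,12435
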
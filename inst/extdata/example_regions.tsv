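region	start	end
dloop	16024	576
coding	577	16023
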
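element,background
As,6.0
Cd,0.35
Pb,59.2
Cr,69
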
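element,residential,industrial
As,34,173
Cd,15,254
Pb,10175,14298
Cr,419,1150
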
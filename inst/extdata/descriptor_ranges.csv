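descriptor,lower,upper
mw,130.0,725.0
logp,-2.0,6.5
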
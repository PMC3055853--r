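definition,a,b,c,d
d1,1805,519,422,1115351
d2,1751,420,476,1115450
d3,1406,251,821,1115619
d4,1295,213,932,1115657
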
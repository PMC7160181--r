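species	clade
m1	monocots
m2	monocots
r1	ranunculales
s1	superrosids
s2	superrosids
s3	superrosids
a1	superasterids
a2	superasterids
a3	superasterids
a4	superasterids
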
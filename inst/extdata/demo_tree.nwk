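((m1:60,m2:60):100,(r1:140,((s1:70,(s2:40,s3:40):30):45,((a1:50,a2:50):40,(a3:80,a4:80):10):25):25):20);
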
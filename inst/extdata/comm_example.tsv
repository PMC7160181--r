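site	m1	r1	s1	s2	a1	a3
plot1	30	5	20	10	25	10
plot2	0	60	10	0	20	10
plot3	10	0	0	40	30	20
plot4	50	10	15	5	10	10
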
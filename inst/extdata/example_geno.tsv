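line	family	c1_m1	c1_m2	c1_m3	c1_m4	c1_m5	c1_m6	c1_m7	c1_m8	c1_m9	c2_m1	c2_m2	c2_m3	c2_m4	c2_m5	c2_m6	c2_m7	c2_m8	c2_m9
line1	An1	B	B	A	A	A	A	A	A	A	B	A	A	A	A	A	A	B	B
line2	An1	A	A	A	B	B	B	B	B	B	B	B	B	B	B	B	B	B	A
line3	An1	A	-	A	A	A	A	A	B	B	B	B	A	A	A	A	A	A	A
line4	An1	A	A	A	A	A	B	B	B	B	B	B	B	B	B	B	B	B	B
line5	An1	A	A	A	A	A	A	A	A	A	A	A	A	A	B	B	B	B	B
line6	An1	A	A	B	B	B	A	B	A	A	A	A	A	A	A	A	A	B	B
line7	An1	B	B	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A
line8	An1	B	B	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A
line9	An1	A	A	A	A	B	B	B	B	B	A	A	A	A	A	A	A	B	B
line10	An1	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B	B	A
line11	An1	A	A	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line12	An1	A	A	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line13	Kas2	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B
line14	Kas2	A	A	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line15	Kas2	B	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A
line16	Kas2	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B	B	B
line17	Kas2	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A	A	A
line18	Kas2	B	B	B	B	B	B	B	B	B	B	B	B	A	B	B	A	A	A
line19	Kas2	B	B	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A
line20	Kas2	B	B	B	B	B	B	-	B	B	A	A	A	A	A	A	A	A	A
line21	Kas2	B	B	B	B	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line22	Kas2	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B
line23	Kas2	B	B	B	B	B	B	B	A	A	B	A	A	A	A	B	B	B	B
line24	Kas2	B	B	B	B	A	A	A	A	A	A	A	A	A	A	B	B	B	B
line25	Kond	B	B	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A
line26	Kond	A	B	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line27	Kond	A	A	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B
line28	Kond	A	B	B	B	B	B	B	B	B	A	A	A	B	B	B	B	B	B
line29	Kond	A	A	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B
line30	Kond	B	B	B	B	B	B	B	B	B	A	A	A	A	B	B	A	A	A
line31	Kond	B	B	B	B	B	B	B	B	B	A	A	H	B	B	B	B	B	B
line32	Kond	B	B	B	B	B	B	B	B	B	A	A	A	A	A	A	A	A	A
line33	Kond	B	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A
line34	Kond	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A
line35	Kond	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B	A
line36	Kond	A	A	A	A	A	A	A	A	A	A	A	A	A	B	B	B	B	B
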
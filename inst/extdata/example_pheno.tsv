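line	family	value
line1	An1	21.364
line2	An1	21.817
line3	An1	21.15
line4	An1	21.756
line5	An1	20.382
line6	An1	21.209
line7	An1	19.529
line8	An1	21.834
line9	An1	20.38
line10	An1	18.796
line11	An1	19.73
line12	An1	22.569
line13	Kas2	23.513
line14	Kas2	15.879
line15	Kas2	15.09
line16	Kas2	19.6
line17	Kas2	21.816
line18	Kas2	19.812
line19	Kas2	23.14
line20	Kas2	22.802
line21	Kas2	21.23
line22	Kas2	23.516
line23	Kas2	22.312
line24	Kas2	19.089
line25	Kond	22.792
line26	Kond	20.572
line27	Kond	20.804
line28	Kond	21.439
line29	Kond	19.992
line30	Kond	24.865
line31	Kond	24.818
line32	Kond	23.193
line33	Kond	19.342
line34	Kond	19.826
line35	Kond	18.36
line36	Kond	17.194
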
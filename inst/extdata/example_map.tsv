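marker	chromosome	position_cM
c1_m1	chr1	0
c1_m2	chr1	5
c1_m3	chr1	10
c1_m4	chr1	15
c1_m5	chr1	20
c1_m6	chr1	25
c1_m7	chr1	30
c1_m8	chr1	35
c1_m9	chr1	40
c2_m1	chr2	0
c2_m2	chr2	5
c2_m3	chr2	10
c2_m4	chr2	15
c2_m5	chr2	20
c2_m6	chr2	25
c2_m7	chr2	30
c2_m8	chr2	35
c2_m9	chr2	40
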
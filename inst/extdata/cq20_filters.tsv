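index	centre_hz	bandwidth_hz
1	200.2	69.3
2	238.3	83.0
3	283.2	98.6
4	336.4	117.2
5	400.4	139.6
6	476.1	166.0
7	565.9	197.3
8	672.3	234.4
9	800.8	278.3
10	952.1	331.1
11	1131.3	394.5
12	1345.2	468.8
13	1600.6	557.6
14	1903.3	663.1
15	2263.7	788.1
16	2690.9	937.5
17	3200.2	1114.3
18	3805.7	1325.2
19	4525.9	1576.2
20	8000.5	6949.2
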
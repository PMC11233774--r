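timestamp_s,id_a,id_b,rssi_db
0.0,C1,T1,-70
2.0,C1,T1,-70
4.0,C1,T1,-70
6.0,C1,T1,-70
8.0,C1,T1,-70
10.0,C1,T1,-70
12.0,C1,T1,-70
14.0,C1,T1,-70
16.0,C1,T1,-70
18.0,C1,T1,-70
20.0,C1,T1,-70
22.0,C1,T1,-70
24.0,C1,T1,-70
26.0,C1,T1,-70
28.0,C1,T1,-70
30.0,C1,T1,-70
10.0,C1,C2,-80
12.0,C2,C1,-80
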
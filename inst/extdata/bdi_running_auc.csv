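position,item,running_auc
1,V1,0.725
2,V14,0.777
3,V7,0.795
4,V9,0.810
5,V10,0.813
6,V15,0.822
7,V17,0.821
8,V8,0.819
9,V20,0.820
10,V5,0.821
11,V3,0.821
12,V4,0.821
13,V13,0.821
14,V12,0.820
15,V2,0.819
16,V19,0.818
17,V18,0.816
18,V6,0.814
19,V16,0.812
20,V11,0.811
21,V21,0.812
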
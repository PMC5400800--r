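item,auc
V1,0.725009
V2,0.631205
V3,0.655666
V4,0.651187
V5,0.658478
V6,0.610004
V7,0.701489
V8,0.667983
V9,0.700461
V10,0.697225
V11,0.597342
V12,0.636791
V13,0.648917
V14,0.707401
V15,0.692064
V16,0.605937
V17,0.674283
V18,0.610028
V19,0.629285
V20,0.666999
V21,0.587468
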
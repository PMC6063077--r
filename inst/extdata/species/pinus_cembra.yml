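name: Pinus cembra
CA0: 327.0
WA0: 41.0
LWA0: 0.0
CTD: 31.0
WT0: 0.5
vc: 0.39
CAmax: 3180.0
WTstar: 1.1
vw: 8.54
WAmax: 915.0
mw: 505.0
sw: 5.58
vl: 7.79
ml: 515.0
sl: 5.63
curve:
  family: quadratic
  a: 1.77
  b: -0.07
  c: 1.6
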
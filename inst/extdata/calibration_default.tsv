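# clashLimit=5
# scoreBreaks=-Inf,0.510084218674901,0.539291303487667,0.594455761240468,0.735713100112172,Inf
# pBreaks=-Inf,0.000289005423780542,0.130373029724245,0.39745185616156,0.590264352799999,Inf
0	0	0	0	0
0	0	0	0	0
0	0	0	0	0
0.5	0.5	0	0	0
1	0.5	0	0	0
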
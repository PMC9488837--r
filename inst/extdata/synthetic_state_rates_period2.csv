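"rate","region"
0.13105,"northeast"
0.05297,"midwest"
0.346629,"west"
0.20185,"midwest"
0.107846,"northeast"
0.123161,"south"
0.055602,"west"
0.115933,"midwest"
0.115515,"west"
0.04687,"west"
0.107572,"northeast"
0.115148,"northeast"
0.102638,"south"
0.084623,"midwest"
0.029097,"midwest"
0.168831,"west"
0.160302,"west"
0.115547,"northeast"
0.083948,"midwest"
0.234494,"south"
0.151762,"northeast"
0.247931,"west"
0.022261,"west"
0.081607,"south"
0.299478,"south"
0.166029,"south"
0.234439,"northeast"
0.143,"west"
0.049504,"northeast"
0.156669,"northeast"
0.139787,"south"
0.264098,"south"
0.138918,"midwest"
0.062524,"south"
0.221945,"northeast"
0.226963,"northeast"
0.107062,"west"
0.379096,"south"
0.073896,"south"
0.098429,"midwest"
0.037854,"northeast"
0.307748,"west"
0.006866,"south"
0.235774,"northeast"
0.115477,"west"
0.063614,"midwest"
0.205765,"midwest"
0.250919,"midwest"
0.16765,"midwest"
0.288132,"midwest"
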
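"rate","region"
0.022261,"northeast"
0.098429,"northeast"
0.063614,"northeast"
0.006866,"northeast"
0.168831,"northeast"
0.049504,"midwest"
0.084623,"south"
0.115547,"northeast"
0.073896,"south"
0.029097,"west"
0.115477,"west"
0.107062,"west"
0.115933,"south"
0.151762,"south"
0.102638,"midwest"
0.037854,"northeast"
0.107846,"midwest"
0.156669,"west"
0.138918,"northeast"
0.04687,"midwest"
0.05297,"midwest"
0.081607,"south"
0.055602,"northeast"
0.062524,"midwest"
0.083948,"west"
0.157358,"south"
0.216555,"west"
0.105389,"south"
0.116308,"midwest"
0.06164,"midwest"
0.05269,"northeast"
0.097402,"west"
0.051081,"south"
0.10058,"west"
0.114296,"west"
0.039299,"midwest"
0.08508,"west"
0.08743,"south"
0.064708,"northeast"
0.125356,"midwest"
0.04679,"west"
0.043021,"midwest"
0.065586,"west"
0.151054,"midwest"
0.142588,"south"
0.105425,"south"
0.039467,"midwest"
0.035877,"northeast"
0.188541,"south"
0.106258,"northeast"
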
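stream,length,area,gradient,precipitation,temperature,runoff,altitude
LY,222,4665,0.57,1598,17.3,39.41,252
MS,296,10305,1.01,1483,18.1,76.03,352
ML,253,5543,0.46,1400,17.6,43.04,250
FS,196,5250,0.79,1275,16.6,43.5,613
XH,419,14700,0.48,1663,16.7,135.1,676
SY,204,4647,0.70,1570,18.8,33,615
SC,176,2882,2.36,1640,16.9,27.1,971
SS,152,1301,2.14,1630,16.7,11.3,1610
HS,256,9103,0.59,1580,17.8,27.4,747
YS,279,6262,0.34,1678,17.2,29.6,391
JJ,307,7886,0.26,1679,17.6,70,391
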
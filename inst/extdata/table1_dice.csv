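scan_id,snake,msd,unet,resnet
3,0.67,0.89,0.86,0.82
4,0.72,0.85,0.79,0.75
5,0.60,0.75,0.78,0.78
6,0.80,0.85,0.88,0.82
7,0.76,0.94,0.93,0.90
8,0.83,0.92,0.91,0.90
9,0.80,0.89,0.87,0.78
10,0.90,0.92,0.92,0.90
11,0.84,0.92,0.92,0.85
12,0.84,0.78,0.69,0.90
13,0.73,0.73,0.78,0.82
14,0.86,0.83,0.88,0.90
15,0.75,0.91,0.90,0.88
16,0.77,0.91,0.92,0.90
17,0.76,0.86,0.91,0.86
18,0.81,0.88,0.94,0.92
19,0.86,0.90,0.87,0.82
20,0.79,0.91,0.90,0.90
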
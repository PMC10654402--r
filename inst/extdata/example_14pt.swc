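# synthetic exemplar: minimal standardized morphology, 14 sample points
# creature mouse
# region neocortex
# coordinate micrometers
1 1 0.0 0.0 0.0 2.5 -1
2 1 2.0 0.0 0.0 3.0 1
3 1 4.0 0.0 0.0 2.5 2
4 3 -2.0 1.0 0.0 1.0 1
5 3 -4.0 3.0 0.0 0.8 4
6 3 -6.0 5.0 0.0 0.6 5
7 3 -4.0 5.0 1.0 0.6 5
8 3 -2.0 -2.0 0.0 1.0 1
9 3 -3.0 -4.0 0.0 0.7 8
10 2 6.0 0.0 0.0 1.2 3
11 2 8.0 2.0 0.0 1.0 10
12 2 10.0 4.0 0.0 0.8 11
13 2 10.0 1.0 0.0 0.8 11
14 2 12.0 6.0 0.0 0.6 12
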
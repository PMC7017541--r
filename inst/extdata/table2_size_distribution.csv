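size,n_groups,n_points
1,305,305
2,68,136
3,22,66
4,18,72
5,11,55
6,5,30
7,5,35
10,4,40
13,3,39
8,3,24
9,2,18
29,1,29
14,1,14
31,1,31
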
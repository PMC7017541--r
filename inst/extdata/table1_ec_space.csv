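point_id,k2,k3,k4,k5,k6,k7,k8,k9,k10,k11
Point 1,c0,c2,c3,c2,c2,c4,c5,c4,c4,c5
Point 2,c0,c0,c3,c3,c2,c4,c4,c4,c4,c2
Point 3,c0,c2,c2,c4,c5,c5,c6,c6,c6,c6
Point 4,c1,c0,c0,c3,c3,c2,c2,c3,c3,c3
Point 5,c0,c0,c3,c3,c2,c2,c4,c2,c2,c2
Point 6,c0,c2,c3,c2,c4,c4,c5,c4,c4,c5
Point 7,c0,c2,c3,c2,c4,c4,c5,c5,c5,c4
Point 8,c0,c2,c2,c4,c4,c5,c6,c6,c6,c6
Point 9,c1,c0,c0,c3,c3,c2,c2,c3,c3,c3
Point 10,c0,c2,c3,c2,c4,c4,c5,c5,c4,c5
Point 11,c0,c2,c2,c2,c4,c5,c6,c5,c5,c4
Point 12,c0,c2,c2,c2,c4,c5,c6,c5,c5,c4
Point 13,c0,c2,c2,c2,c4,c5,c6,c5,c5,c4
Point 14,c0,c2,c3,c2,c2,c4,c5,c4,c4,c5
Point 15,c0,c2,c2,c2,c4,c5,c6,c5,c5,c4
Point 16,c0,c2,c3,c2,c4,c4,c5,c5,c4,c5
Point 17,c0,c2,c3,c2,c4,c5,c5,c5,c5,c4
Point 18,c0,c2,c3,c2,c2,c4,c5,c4,c4,c5
Point 19,c0,c0,c3,c3,c2,c2,c4,c2,c2,c2
Point 20,c0,c2,c2,c2,c4,c5,c6,c5,c5,c4
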
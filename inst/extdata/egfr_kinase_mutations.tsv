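mutation	site
P694L(1) P694S(1)	lung
S695G(1)	thyroid
I706T(1)	lung
K708M(1)	lung
E709A(8) E709G(4) E709H(2) E709K(9) E709V(2)	lung; prostate
E711K(1)	lung
W731R(1)	lung
P733L(1) P733S(1) P733T(1)	lung
G735S(3)	prostate; lung
V738G(2)	prostate
P741H(1) P741L(2)	thyroid; central_nervous_system
S768C(1) S768I(21) S768I(23) S768N(1)	lung; oesophagus; central_nervous_system
S784F(2) S784P(1) S784Y(1)	lung; upper_aerodigestive_tract
V802F(2) V802I(1)	lung; upper_aerodigestive_tract
G810D(2) G810S(1)	upper_aerodigestive_tract; lung
P848L(3) P848L(4)	upper_aerodigestive_tract; lung
L861F(1) L861P(1) L861Q(26) L861Q(30) L861R(5) L861R(3) L861V(1)	lung; central_nervous_system
F968L(1)	central_nervous_system
D1012H(1)	lung
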
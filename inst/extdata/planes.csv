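name,description,landmarks,roles_ceph19,roles_ceph45
SN,Anterior cranial base plane,S-N,1;2,39;1
FH,Frankfort horizontal plane,P-Or,4;3,44;29
Bolton,Bolton plane,Bolton-N,,43;1
Palatal,Palatal plane,ANS-PNS,18;17,5;37
CranialBase,Cranial base plane,Ba-N,,42;1
MP,Mandibular plane,Go-Me,10;8,17;18
RP,Ramal plane,Ar-Go,19;10,41;17
NP,Facial plane,N-Pg,2;7,1;20
NA,NA plane,N-A,2;5,1;6
AB,Subspinale to infradentale plane,A-B,5;6,6;22
AP,AP plane,A-Pg,5;7,6;20
SoftFacial,Facial plane of soft tissue,Ns-Pos,,2;14
EP,Ricketts esthetic plane,Prn-Pos,,3;14
H,H plane,UL-Pos,13;16,9;14
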
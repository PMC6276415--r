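name,class,roles,unit,variant
SNA,angle3,39;1;6,deg,
SNB,angle3,39;1;22,deg,
ANB,angle3,6;1;22,deg,
SNPg,angle3,39;20;1,deg,
NAPg,angle3,1;6;20,deg,
NSGn,angle3,1;39;19,deg,
Ns-Prn-Pos,angle3,2;3;14,deg,
Cm-Sn-UL,angle3,4;7;9,deg,
LL-B'-Pos,angle3,12;13;14,deg,
Angle of the jaw,angle3,41;17;18,deg,
Angle of convexity,angle3,2;7;14,deg,
FH-SN,angle2planes,44;29;39;1,deg,unsigned
UI-SN,angle2planes,28;25;39;1,deg,unsigned
LI-FH,angle2planes,24;21;44;29,deg,unsigned
UI-LI,angle2planes,28;25;24;21,deg,unsigned
H angle,angle2planes,9;14;8;14,deg,unsigned
Z angle,angle2planes,44;29;9;14,deg,rear_lower
N-Me,dist2pts,1;18,mm,
N-ANS,dist2pts,1;5,mm,
ANS-Me,dist2pts,5;18,mm,
Stoms-UI,dist2pts,10;25,mm,
UI-AP,distPtPlane,25;6;20,mm,signed
LI-AP,distPtPlane,24;6;20,mm,signed
UL-EP,distPtPlane,9;3;14,mm,signed
LL-EP,distPtPlane,12;3;14,mm,signed
Max.E,distPtPlane,6;5;37,mm,unsigned
Wits,distProjected,6;22;32;34,mm,
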
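name,class,roles,unit,variant
ANB,angle3,5;2;6,deg,
SNB,angle3,1;2;6,deg,
SNA,angle3,1;2;5,deg,
ODI,composite_odi,5;6;8;10;17;18;4;3,deg,
APDI,composite_apdi,3;4;2;7;5;6;17;18,deg,
FHI,composite_fhi,1;10;2;8,ratio,
FHA,angle2planes,1;2;10;9,deg,unsigned
MW,composite_mw,12;11,mm,
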
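measurement,type,label,kind,lo,hi
ANB,1,class I (normal),range,3.2,5.7
ANB,2,class II,gt,5.7,
ANB,3,class III,lt,,3.2
SNB,1,normal mandible,range,74.6,78.7
SNB,2,retrognathic mandible,lt,,74.6
SNB,3,prognathic mandible,gt,78.7,
SNA,1,normal maxilla,range,79.4,83.2
SNA,2,prognathic maxilla,gt,83.2,
SNA,3,retrognathic maxilla,lt,,79.4
ODI,1,normal,range,68.43,80.57
ODI,2,deep bite tendency,gt,80.5,
ODI,3,open bite tendency,lt,,68.4
APDI,1,normal,range,77.6,85.2
APDI,2,class II tendency,lt,,77.6
APDI,3,class III tendency,gt,85.2,
FHI,1,normal,range,0.65,0.75
FHI,2,short face tendency,gt,0.75,
FHI,3,long face tendency,lt,,0.65
FHA,1,normal,range,26.8,31.4
FHA,2,mandible high angle tendency,gt,31.4,
FHA,3,mandible lower angle tendency,lt,,26.8
MW,1,normal,range,2,4.5
MW,2,edge to edge,eq,0,
MW,3,anterior cross bite,lt,,0
MW,4,large over jet,gt,4.5,
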
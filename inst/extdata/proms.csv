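participant,instrument,timepoint,score
B,OHS,BL,18
B,OHS,FU1,23
B,OHS,FU2,35
B,OHS,FU3,42
C,OHS,BL,32
C,OHS,FU1,33
C,OHS,FU2,47
C,OHS,FU3,47
B,HOOS-QOL,BL,37.5
B,HOOS-QOL,FU1,37.5
B,HOOS-QOL,FU2,62.5
B,HOOS-QOL,FU3,100
C,HOOS-QOL,BL,68.75
C,HOOS-QOL,FU1,62.5
C,HOOS-QOL,FU2,75
C,HOOS-QOL,FU3,75
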
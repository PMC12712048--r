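word,abbreviation
MOUNTAIN,MTN
MOUNTAINS,MTNS
CANYON,CYN
CREEK,CRK
RIVER,RIV
LAKE,LK
LAKES,LKS
VALLEY,VLY
RIDGE,RDG
SPRING,SPG
SPRINGS,SPGS
JUNCTION,JCT
MEADOW,MDW
MEADOWS,MDWS
RANCH,RNCH
HEIGHTS,HTS
HIGHWAY,HWY
CENTER,CTR
CROSSING,XING
ESTATES,EST
FALLS,FLS
FOREST,FRST
GROVE,GRV
HARBOR,HBR
HILL,HL
HILLS,HLS
ISLAND,IS
LANDING,LNDG
LODGE,LDG
MISSION,MSN
ORCHARD,ORCH
PLAINS,PLNS
POINT,PT
PRAIRIE,PR
STATION,STA
SUMMIT,SMT
TRAIL,TRL
VIEW,VW
VILLAGE,VLG
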
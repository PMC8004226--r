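compound_id,molweight,cLogP,H.acceptors,H.donors,polar.surface.area,rotatable.bonds,aromatic.rings,natoms,total.surface.area,Lipinski..violations,Veber..violations,Muegge..violations,Egan..violations,Ghose..violations
navitoclax,974.6,8.25,10,2,168,16,4,66,402,2,2,3,2,2
abt737,813.4,7.5,10,3,162,16,5,56,368,2,2,3,2,2
tunicamycin,844.9,-1.6,20,12,345,16,0,58,355,3,2,4,1,2
ginsenoside_rb1,1109.3,-0.4,23,15,373,17,0,78,473,3,2,4,1,2
azithromycin,749.0,3.2,14,5,180,7,0,52,332,2,1,2,1,2
roxithromycin,837.0,2.9,15,5,217,9,0,58,362,2,1,3,1,2
timosaponin_a3,740.9,2.2,13,8,208,5,0,51,324,2,1,3,1,2
digoxin,780.9,1.9,14,6,203,7,0,55,338,2,1,3,1,2
rapamycin,914.2,6.0,13,3,195,6,0,65,396,2,1,3,2,2
dasatinib,488.0,3.6,8,3,135,8,3,33,248,0,0,0,1,1
quercetin,302.2,1.5,7,5,131,1,3,22,166,0,0,0,0,0
fisetin,286.2,1.8,6,4,111,1,3,21,158,0,0,0,0,0
piperlongumine,317.3,1.6,4,0,66,4,1,23,182,0,0,0,0,0
luteolin,286.2,2.5,6,4,111,1,3,21,160,0,0,0,0,0
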
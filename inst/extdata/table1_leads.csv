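compound_id,name,pubchem_cid,kmeans_coefficient
navitoclax,Navitoclax,24978538,0.44
abt737,ABT 737,11228183,0.58
tunicamycin,Tunicamycin,56927848,0.34
ginsenoside_rb1,Ginsenoside Rb1,9898279,0.31
azithromycin,Azithromycin,447043,0.32
roxithromycin,Roxithromycin,6915744,0.23
timosaponin_a3,Timosaponin A-III,15953793,0.29
digoxin,Digoxin,2724385,0.21
rapamycin,Rapamycin,5284616,-0.2
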
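class_id,service_id,value,unit
1,food,0,pct
2,food,0,pct
3,food,60,pct
4,food,100,pct
5,food,60,pct
6,food,40,pct
7,food,40,pct
8,food,40,pct
1,marketable,20,pct
2,marketable,100,pct
3,marketable,80,pct
4,marketable,60,pct
5,marketable,40,pct
6,marketable,20,pct
7,marketable,20,pct
8,marketable,40,pct
1,fuelwood,20,pct
2,fuelwood,40,pct
3,fuelwood,60,pct
4,fuelwood,60,pct
5,fuelwood,80,pct
6,fuelwood,60,pct
7,fuelwood,0,pct
8,fuelwood,100,pct
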
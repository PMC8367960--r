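year,animal,count,origin
2019,horse_mule,100,migratory
2019,sheep,200,migratory
2019,goat,100,migratory
2019,cow,500,local
2019,horse_mule,100,local
2019,goat,200,local
2019,sheep,145,local
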
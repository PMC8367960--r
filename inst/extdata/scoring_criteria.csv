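variable,category,level,lower,upper
pH,E,satisfactory,4.7,5.3
pH,E,average,4.0,6.0
pH,E,not_satisfactory,,4.0
pH,E,not_satisfactory,6.0,
OC,E,satisfactory,7.5,
OC,E,average,5.0,7.5
OC,E,not_satisfactory,,5.0
N,E,satisfactory,0.75,
N,E,average,0.50,0.75
N,E,not_satisfactory,,0.50
P,E,satisfactory,0.50,
P,E,average,0.25,0.50
P,E,not_satisfactory,,0.25
K,E,satisfactory,2,
K,E,average,1,2
K,E,not_satisfactory,,1
WHC,E,satisfactory,50,60
WHC,E,average,40,50
WHC,E,average,60,70
WHC,E,not_satisfactory,,40
WHC,E,not_satisfactory,70,
vegetation_cover,E,satisfactory,60,
vegetation_cover,E,average,30,60
vegetation_cover,E,not_satisfactory,,30
grazing_control,M,satisfactory,,285
grazing_control,M,average,285,857
grazing_control,M,not_satisfactory,857,
tourist_control,M,satisfactory,,65
tourist_control,M,average,65,200
tourist_control,M,not_satisfactory,200,
erosion_control,M,satisfactory,,5
erosion_control,M,average,5,35
erosion_control,M,not_satisfactory,35,
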
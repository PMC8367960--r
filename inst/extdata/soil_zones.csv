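zone,variable,mean,se
R,herb_density,19.77,0.04
GTZ,herb_density,10.56,0.02
UTZ,herb_density,3.7,0.05
R,pH,5.15,0.24
GTZ,pH,4.96,0.28
UTZ,pH,4.69,0.21
R,OC,6.64,0.26
GTZ,OC,4.83,0.04
UTZ,OC,3.76,0.14
R,N,0.133,0.01
GTZ,N,0.09,0.03
UTZ,N,0.047,0.02
R,P,0.35,0.04
GTZ,P,0.29,0.03
UTZ,P,0.14,0.01
R,K,0.81,0.02
GTZ,K,0.78,0.04
UTZ,K,0.26,0.02
R,WHC,56.96,0.13
GTZ,WHC,49.85,0.13
UTZ,WHC,47.76,0.59
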
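species,density,biomass_g_per_m2,yield_printed_quintal,palatable,ambiguous
Aconogonum tortuosum,0.4,4.2,177.86,TRUE,FALSE
Anemone obtusiloba,0.23,2.68,113.49,TRUE,FALSE
Arnebia benthamii,0.06,12.85,42.04,TRUE,TRUE
Bistorta vivipara,9.8,16.8,711.43,TRUE,FALSE
Bupleurum longicaule,0.2,1.3,55.05,TRUE,FALSE
Carex nubigena,4.42,1.5,63.52,TRUE,FALSE
Carex setigera,0.82,7.2,304.90,TRUE,FALSE
Cyananthus lobatus,0.57,6.1,258.32,TRUE,FALSE
Dactylorhiza hatagirea,0.23,1.3,55.05,TRUE,FALSE
Danthonia cachemyriana,0.33,60.2,2549.30,TRUE,FALSE
Epilobium latifolium,0.24,1.1,46.58,TRUE,FALSE
Eritrichium canum,0.62,1.2,50.82,TRUE,FALSE
Euphorbia stracheyi,0.2,1.4,59.29,TRUE,FALSE
Galium rotundifolium,0.23,0.2,8.47,TRUE,FALSE
Gentiana argentea,0.23,0.8,33.88,TRUE,FALSE
Geranium wallichianum,0.3,0.9,38.11,TRUE,FALSE
Geum elatum,0.2,1.2,50.82,TRUE,FALSE
Impatiens scabrida,0.31,1.3,55.05,TRUE,FALSE
Origanum vulgare,1.22,4.3,182.09,TRUE,FALSE
Oxygraphis polypetala,0.02,1.4,59.29,TRUE,FALSE
Parnassia nubicola,0.27,3.4,143.98,TRUE,FALSE
Picrorhiza kurrooa,0.08,1.2,50.82,TRUE,FALSE
Poa alpina,0.23,1.1,46.58,TRUE,FALSE
Polygonum polystachyum,0.4,1.8,76.22,TRUE,FALSE
Potentilla argyrophylla,0.5,2.2,93.16,TRUE,FALSE
Potentilla atrosanguinea,0.3,2.1,88.93,TRUE,FALSE
Potentilla fulgens,0.13,1.7,71.99,TRUE,FALSE
Primula denticulata,0.4,2.9,122.81,TRUE,FALSE
Prunella vulgaris,4.43,6.3,266.79,TRUE,FALSE
Ranunculus hyperboreus,0.4,6.1,258.32,TRUE,FALSE
Rumex nepalensis,1.19,10.8,457.35,TRUE,FALSE
Salix lindleyana,0.01,22.6,957.04,TRUE,FALSE
Taraxacum officinale,9.79,15.04,636.90,TRUE,FALSE
Trachydium roylei,19.33,22.2,940.11,TRUE,FALSE
Trifolium repens,0.53,4.2,177.86,TRUE,FALSE
Valeriana hardwickii,0.04,0.5,21.17,TRUE,FALSE
Viola biflora,4.24,4.2,177.86,TRUE,FALSE
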
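name,role,TL_ref,B,PB,QB,EE_ref
Conger myriaster,consumer,3.71,0.2785,0.90,4.80,0.107
Sebastes schlegelii,consumer,3.73,0.1175,0.90,6.80,0.000
Hexagrammos otakii,consumer,3.50,1.3290,0.70,3.40,0.313
Flatfish,consumer,3.50,0.2610,1.12,3.80,0.148
Other demersal fishes,consumer,2.83,1.3178,1.30,9.30,0.950
Crustaceans,consumer,2.81,77.36,5.60,16.90,0.821
Echinoderms,consumer,2.64,42.72,1.30,3.70,0.482
Cephalopods,consumer,3.52,0.16,2.90,12.00,0.950
Polychaetes,consumer,2.11,3.80,6.75,20.60,0.610
Carnivorous gastropods,consumer,3.11,105.08,0.26,2.82,0.007
Oyster,consumer,2.08,1333,1.23,7.75,0.159
Other mollusks,consumer,2.28,161.29,4.40,17.20,0.594
Other benthos,consumer,2.16,59.61,6.40,27.80,0.769
Benthic algae,producer,1.00,54.49,50.55,,0.950
Zooplankton,consumer,2.05,23.38,73.00,122.10,0.950
Phytoplankton,producer,1.00,38.60,209.70,,0.950
Detritus,detritus,1.00,130.00,,,0.961
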
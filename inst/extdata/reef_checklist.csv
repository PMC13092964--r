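phylum,species
Mollusca,Magallana gigas
Mollusca,Patelloida pygmaea
Mollusca,Nipponacmea schrenckii
Mollusca,Cellana toreuma
Mollusca,Littoraria intermedia
Mollusca,Chlorostoma rustica
Mollusca,Batillaria cumingi
Mollusca,Nassarius variciferus
Mollusca,Rapana venosa
Mollusca,Ceratostoma rorifluum
Mollusca,Reishia clavigera
Mollusca,Mytilus edulis
Mollusca,Trapezium liratum
Mollusca,Ruditapes philippinarum
Mollusca,Acanthochiton rubrolineatus
Mollusca,Littorina brevicula
Echinodermata,Asterina pectinifera
Nemertea,Amphiporus punctatulus
Arthropoda,Fistulobalanus albicostatus
Arthropoda,Gaetice depressus
Arthropoda,Photis longicaudata
Annelida,Marphysa sanguinea
Annelida,Lumbrineris latreilli
Annelida,Nereis longior
Annelida,Neanthes japonica
Annelida,Perinereis aibuhiensis
Annelida,Haploscoloplos elongatus
Annelida,Mediomastus californiensis
Annelida,Notomastus aberans
Annelida,Arenicola brasiliensis
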
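category,species,A,B,C
zooplankton,Calanus sinicus,1,3,9
zooplankton,Paracalanus parvus,2,0,6
zooplankton,Acartia pacifica,0,1,1
zooplankton,Cirripedia nauplius larvae,0,1,3
zooplankton,Oikopleura dioica,0,4,0
zooplankton,Centropages abdominalis,3,0,0
zooplankton,Euphausia diomedeaea zoea larvae,0,2,0
zooplankton,Aidanosagitta crassa,0,1,0
zooplankton,Brachyura zoea larvae,0,0,1
phytoplankton,Paralia sulcata,0,0,180
phytoplankton,Licmophora abbreviata,24,18,43
phytoplankton,Synedra sp.,54,7,17
phytoplankton,Nitzschia sp.,1,6,12
phytoplankton,Nitzschia closterium,18,0,0
phytoplankton,Pseudo-nitzschia pungens,4,0,5
phytoplankton,Nitzschia lorenziana,7,0,0
phytoplankton,Skeletonema costatum,0,0,5
phytoplankton,Guinardia delicatula,0,0,4
phytoplankton,Coscinodiscus sp.,0,1,2
phytoplankton,Rhizosolenia setigera,1,0,0
phytoplankton,Pleurosigma sp.,0,1,0
phytoplankton,Navicula sp.,0,0,1
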
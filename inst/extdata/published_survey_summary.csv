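aoi,dams,active_channel_km,dammed_reaches,active_reaches
Tay,41,221.35,NA,NA
Otter,35,34.58,NA,NA
Coombeshead,13,1.65,NA,NA
All,89,257.58,58,2104
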
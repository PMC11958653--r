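model,n_classes,feature
multinomial,3,AreaGSR
multinomial,3,NoPeakes
multinomial,3,avgRiseTime
multinomial,3,avgDecayTime
multinomial,3,STDGSRdata
multinomial,3,STDSCRdata
multinomial,3,spectralEnergy
multinomial,3,MEAN_RR
multinomial,3,SDRR
multinomial,3,SDSD
multinomial,3,SDRR_RMSSD
multinomial,3,HR
multinomial,3,pNN25
multinomial,3,LF_HF
multinomial,3,HF_LF
visual_vs_baseline,2,AreaGSR
visual_vs_baseline,2,NoPeakes
visual_vs_baseline,2,STDGSRdata
visual_vs_baseline,2,STDSCRdata
visual_vs_baseline,2,spectralEnergy
visual_vs_baseline,2,bandPower
visual_vs_baseline,2,MEAN_RR
visual_vs_baseline,2,SDSD
visual_vs_baseline,2,HR
visual_vs_baseline,2,pNN25
visual_vs_baseline,2,pNN50
visual_vs_baseline,2,LF_HF
code_vs_baseline,2,AreaSCR
code_vs_baseline,2,NoPeakes
code_vs_baseline,2,STDGSRdata
code_vs_baseline,2,spectralEnergy
code_vs_baseline,2,bandPower
code_vs_baseline,2,RMSSD
code_vs_baseline,2,MEDIAN_RR
code_vs_baseline,2,SDRR
code_vs_baseline,2,HR
code_vs_baseline,2,pNN25
code_vs_baseline,2,KURT_RR
code_vs_baseline,2,VLF
code_vs_baseline,2,LF
code_vs_visual,2,NoPeakes
code_vs_visual,2,avgDecayTime
code_vs_visual,2,STDGSRdata
code_vs_visual,2,STDSCRdata
code_vs_visual,2,spectralEnergy
code_vs_visual,2,MEAN_RR
code_vs_visual,2,SDSD
code_vs_visual,2,SDRR_RMSSD
code_vs_visual,2,HR
code_vs_visual,2,pNN50
code_vs_visual,2,KURT_RR
code_vs_visual,2,SD2
code_vs_visual,2,LF_HF
code_vs_visual,2,HF_LF
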
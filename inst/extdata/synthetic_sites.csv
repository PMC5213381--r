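pig_id,group,thickness_mm,peak_voltages_v,peak_currents_a,arcing
pig01,50J,4,986.7101202,30.47031105,FALSE
pig01,100J,5,618.408049,25.31145244,FALSE
pig01,4x50J,10,752.1147194;748.090518;764.5511491;763.3768166,27.44333533;27.29649934;27.89711864;27.85426933,FALSE
pig02,50J,8,887.4603681,22.88825641,FALSE
pig02,100J,9,1215.553862,36.79806724,FALSE
pig02,4x50J,12,803.6348679;811.6669306;810.70154;786.3055621,23.96274256;24.20224218;24.17345622;23.44601822,FALSE
pig03,50J,6,799.1457067,23.64046276,FALSE
pig03,100J,10,979.9943549,32.82698146,FALSE
pig03,4x50J,10,371.9553711;388.326255;382.2185959;391.0744164,19.23455898;20.08113025;19.76529093;20.22324319,FALSE
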
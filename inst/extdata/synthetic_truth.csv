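pig_id,group,true_threshold_a_cm2,pig_effect,delivered_center_a_cm2,success
pig01,50J,4.455189183971571,0.15518918397157136,5.226656752988802,TRUE
pig01,100J,5.255189183971571,0.15518918397157136,4.145152186700767,FALSE
pig01,4x50J,3.512332041114428,0.15518918397157136,3.5373554951709223,TRUE
pig02,50J,4.308910350927753,0.008910350927752782,3.24166205824135,FALSE
pig02,100J,5.1089103509277525,0.008910350927752782,4.957250292623703,FALSE
pig02,4x50J,3.3660532080706096,0.008910350927752782,2.7672867309834777,FALSE
pig03,50J,4.493288621085741,0.1932886210857414,3.692072431711353,FALSE
pig03,100J,5.2932886210857415,0.1932886210857414,4.203798292361006,FALSE
pig03,4x50J,3.550431478228598,0.1932886210857414,2.5389096397172923,FALSE
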
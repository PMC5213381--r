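pig_id,group,section,necrotic_halfwidth_mm,transition_halfwidth_mm,contains_vital_inside,spans_between_paddles
pig01,50J,1,9.975039939,11.84337501,TRUE,TRUE
pig01,50J,2,9.269012483,12.25608471,TRUE,TRUE
pig01,50J,3,8.82105836,11.13656253,TRUE,TRUE
pig01,50J,4,9.888402034,11.23661285,TRUE,TRUE
pig01,100J,1,0,5.999609745,TRUE,FALSE
pig01,100J,2,0,5.406858378,FALSE,FALSE
pig01,100J,3,0,5.598634245,FALSE,FALSE
pig01,100J,4,0,6.082892395,FALSE,FALSE
pig01,4x50J,1,1.184966881,8.704928482,FALSE,TRUE
pig01,4x50J,2,1.959749087,9.901748892,FALSE,TRUE
pig02,50J,1,0,1.346383691,TRUE,FALSE
pig02,50J,2,0,2.129824002,TRUE,FALSE
pig02,100J,1,0,8.61459625,TRUE,FALSE
pig02,100J,2,0,9.597180352,FALSE,FALSE
pig02,100J,3,0,8.576004181,FALSE,FALSE
pig02,100J,4,0,9.448201891,FALSE,FALSE
pig02,4x50J,1,0,5.55486822,FALSE,FALSE
pig02,4x50J,2,0,5.714353103,FALSE,FALSE
pig02,4x50J,3,0,5.386993438,FALSE,FALSE
pig03,50J,1,0,6.767996488,TRUE,FALSE
pig03,50J,2,0,6.541269376,TRUE,FALSE
pig03,50J,3,0,7.836737442,TRUE,FALSE
pig03,100J,1,0,5.53821327,TRUE,FALSE
pig03,100J,2,0,5.577457911,TRUE,FALSE
pig03,100J,3,0,5.243116012,FALSE,FALSE
pig03,100J,4,0,5.759520848,TRUE,FALSE
pig03,4x50J,1,0,0,FALSE,FALSE
pig03,4x50J,2,0,0,FALSE,FALSE
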
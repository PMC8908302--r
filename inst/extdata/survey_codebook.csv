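item,scale,min,max,loading_full,retained,standalone,label
pc01,pro_community,1,5,0.85,TRUE,FALSE,attachment to the community
pc02,pro_community,1,5,0.81,TRUE,FALSE,keeping local traditions
pc03,pro_community,1,5,0.81,TRUE,FALSE,trust toward community members
pc04,pro_community,1,5,0.76,TRUE,FALSE,perceived honesty of members
pc05,pro_community,1,5,0.69,TRUE,FALSE,following community rules
pc06,pro_community,1,5,0.69,TRUE,FALSE,helping members in need
pc07,pro_community,1,5,0.68,TRUE,FALSE,treating neighbors to meals
pc08,pro_community,1,5,0.56,FALSE,TRUE,participation in community activities
pc09,pro_community,1,5,0.39,FALSE,FALSE,obligation to reciprocate favors
op01,openness,1,5,0.83,TRUE,FALSE,welcoming outside values
op02,openness,1,5,0.66,TRUE,FALSE,creating new culture beyond tradition
op03,openness,1,5,0.75,TRUE,FALSE,welcoming settlers from abroad
op04,openness,1,5,0.59,TRUE,FALSE,welcoming settlers from elsewhere
op05,openness,1,5,-0.09,FALSE,FALSE,worry that newcomers bring problems
hap01,happiness,0,10,NA,TRUE,TRUE,current happiness rating
hea01,subjective_health,0,10,NA,TRUE,TRUE,current health rating
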
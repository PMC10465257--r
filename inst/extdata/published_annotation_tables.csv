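rater_id,tier,round_id,dsc,tnr,tpr,precision,n_areas
Ex1,expert,1,0.9078,1,0.8312,1,411
Ex2,expert,1,0.9336,0.9996,0.8983,0.9719,285
Jr1,junior,1,0.7195,0.9981,0.6321,0.8451,219
Jr2,junior,1,0.5527,0.9993,0.3943,0.9456,254
Jr3,junior,1,0.7359,0.9993,0.6039,0.9491,307
Ex2,expert,2,0.9375,1,0.8825,1,285
Jr1,junior,2,0.7235,0.9981,0.6373,0.8435,191
Jr2,junior,2,0.5827,0.9979,0.4575,0.8291,111
Jr3,junior,2,0.6267,0.9993,0.4725,0.9482,336
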
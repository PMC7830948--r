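name,goal,lower,upper,lower_weight,upper_weight,importance
plga,in_range,33.3,100,1,1,3
lecithin,in_range,66.7,200,1,1,3
poloxamer,in_range,0.5,1.5,1,1,3
particle_size,minimize,139,210,1,1,1
ee,maximize,58.7,75.6,1,1,5
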
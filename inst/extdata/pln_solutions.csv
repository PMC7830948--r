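solution,plga,lecithin,poloxamer,particle_size_pred,ee_pred,desirability,selected
1,72.1,86.8,1.5,139.089,75.6,1,FALSE
2,67.5,69.9,1.5,141.145,75.6002,1,TRUE
3,70.9,78.6,1.4,141.817,75.6,1,FALSE
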
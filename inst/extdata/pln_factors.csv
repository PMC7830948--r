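name,units,low,center,high
plga,mg in 100 mL,33.34,66.67,100
lecithin,mg in 100 mL,66.67,133.34,200
poloxamer,% w/v,0.5,1.0,1.5
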
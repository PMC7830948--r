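run_id,plga_coded,lecithin_coded,poloxamer_coded,plga_actual,lecithin_actual,poloxamer_actual,particle_size,particle_size_sd,ee,ee_sd
PLNs-01,-1,-1,0,33.34,66.67,1.0,153,0.50,59.1,0.15
PLNs-02,1,-1,0,100,66.67,1.0,155,1.00,71,0.58
PLNs-03,-1,1,0,33.34,200,1.0,172,0.76,61,0.20
PLNs-04,1,1,0,100,200,1.0,210,1.53,65.5,0.75
PLNs-05,-1,0,-1,33.34,133.34,0.5,154,1.00,58.7,0.61
PLNs-06,1,0,-1,100,133.34,0.5,152,0.58,67.5,1.00
PLNs-07,-1,0,1,33.34,133.34,1.5,140,1.00,60,0.55
PLNs-08,1,0,1,100,133.34,1.5,159,1.00,69.3,1.15
PLNs-09,0,-1,-1,66.67,66.67,0.5,140,0.58,74.2,0.20
PLNs-10,0,1,-1,66.67,200,0.5,191,1.00,72.1,0.51
PLNs-11,0,-1,1,66.67,66.67,1.5,139,0.58,75.6,0.25
PLNs-12,0,1,1,66.67,200,1.5,163,1.53,72,0.61
PLNs-13,0,0,0,66.67,133.34,1.0,150,0.58,73,0.25
PLNs-14,0,0,0,66.67,133.34,1.0,151,1.00,72.7,0.20
PLNs-15,0,0,0,66.67,133.34,1.0,149,0.58,73.4,0.25
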
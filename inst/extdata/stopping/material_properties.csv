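name,density_g_cm3,z_over_a,radiation_length_g_cm2,is_metal
water,1,0.55509,36.08,FALSE
air,0.001205,0.49919,36.62,FALSE
tungsten,19.3,0.402524,6.76,TRUE
nickel,8.902,0.477055,12.68,TRUE
lead,11.35,0.395753,6.37,TRUE
polycarbonate,1.2,0.52697,41.5,FALSE
brass,8.52,0.45711,12.73,TRUE
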
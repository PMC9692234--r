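parameter,value
fluence_to_dose_Gy_cm2,3.5e-11
isotropic_fraction,0.5
forward_fraction,0.5
forward_cos_exponent,8
block_to_phantom_mm,50
phantom_radius_mm,100
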
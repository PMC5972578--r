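factor,level,thousand_grain_weight_g
temperature,control_20C,40.06
temperature,high_28C,28.09
nitrogen,high,35.08
nitrogen,low,33.07
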
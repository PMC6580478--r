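criterion,weight,diffused_led_plate,electroluminescent_ribbons,led_strip
shadow,2,0,0,+
power_required,1,0,0,-
shape,1,0,+,+
buy_make,1,0,0,+
price,1,0,-,0
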
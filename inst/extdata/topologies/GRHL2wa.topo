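Source Target Type
SNAIL ZEB 1
miR200 ZEB 2
ZEB miR200 2
ZEB GRHL2 2
GRHL2 ZEB 2
miR200 GRHL2 1
ZEB ZEB 1
GRHL2 GRHL2 1
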
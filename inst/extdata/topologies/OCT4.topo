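Source Target Type
SNAIL ZEB 1
SNAIL miR145 1
miR200 ZEB 2
ZEB miR200 2
ZEB miR145 2
miR145 OCT4 2
OCT4 miR200 1
OCT4 miR145 1
ZEB OCT4 1
miR145 miR145 2
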
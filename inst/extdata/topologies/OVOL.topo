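Source Target Type
SNAIL miR200 2
SNAIL ZEB 1
miR200 ZEB 2
ZEB miR200 2
ZEB OVOL 2
OVOL ZEB 2
miR200 OVOL 1
OVOL miR200 1
OVOL OVOL 2
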
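Source Target Type
Signal SNAIL 1
SNAIL miR34 2
miR34 SNAIL 2
SNAIL miR200 2
SNAIL ZEB 1
miR200 ZEB 2
ZEB miR200 2
miR34 ZEB 2
ZEB miR34 2
ZEB Ecad 2
Ecad ZEB 2
miR200 KEAP1 2
KEAP1 NRF2 2
NRF2 SNAIL 2
NRF2 Ecad 1
NRF2 miR200 1
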
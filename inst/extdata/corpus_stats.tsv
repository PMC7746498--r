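corpus	item	count
IULA	sentences	3194
IULA	annotated_sentences	1093
IULA	negated_entities	1456
SFU	sentences	9455
SFU	annotated_sentences	3022
SFU	negated_entities	3941
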
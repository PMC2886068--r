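species,character,state
lobe_finned_fish,C27_alcohol_present,present
lobe_finned_fish,C27_acid_present,absent
lobe_finned_fish,C24_acid_present,absent
Mammalia,C27_alcohol_present,absent
Mammalia,C27_acid_present,absent
Mammalia,C24_acid_present,present
Testudines,C27_alcohol_present,present
Testudines,C27_acid_present,present
Testudines,C24_acid_present,absent
Crocodylia,C27_alcohol_present,absent
Crocodylia,C27_acid_present,present
Crocodylia,C24_acid_present,absent
Aves,C27_alcohol_present,present
Aves,C27_acid_present,present
Aves,C24_acid_present,present
tuatara,C27_alcohol_present,absent
tuatara,C27_acid_present,present
tuatara,C24_acid_present,absent
lizards,C27_alcohol_present,absent
lizards,C27_acid_present,present
lizards,C24_acid_present,present
snakes,C27_alcohol_present,absent
snakes,C27_acid_present,absent
snakes,C24_acid_present,present
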
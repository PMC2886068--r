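(lobe_finned_fish,(Mammalia,((Testudines,(Crocodylia,Aves))B,(tuatara,(lizards,snakes))C))Amniota)A;
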
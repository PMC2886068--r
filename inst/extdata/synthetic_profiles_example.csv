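species,family,order_group,diet,compound,percent
Crotalus_demo,Viperidae,Serpentes,carnivore,cholic acid,~100
Python_demo,Pythonidae,Serpentes,carnivore,pythocholic acid,55
Python_demo,Pythonidae,Serpentes,carnivore,cholic acid,30
Python_demo,Pythonidae,Serpentes,carnivore,deoxycholic acid,12
Varanus_demo,Varanidae,Anguimorpha,carnivore,varanic acid,90
Varanus_demo,Varanidae,Anguimorpha,carnivore,cholic acid,8
Loxodonta_demo,Elephantidae,Paenungulata,herbivore,5b-cyprinol sulfate,97
Sus_demo,Suidae,Artiodactyla,omnivore,hyocholic acid,60
Sus_demo,Suidae,Artiodactyla,omnivore,chenodeoxycholic acid,25
Sus_demo,Suidae,Artiodactyla,omnivore,"3a,7a,12a-trihydroxy-5b-cholestan-27-oic acid",11
Alligator_demo,Alligatoridae,Crocodylia,carnivore,"tauro-3a,7a,12a-trihydroxy-5b-cholestan-27-oic acid",85
Alligator_demo,Alligatoridae,Crocodylia,carnivore,taurochenodeoxycholic acid,10
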
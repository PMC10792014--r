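(Blan:2.2,(Cint:1.9,((Pmar:1.2,Ebur:1.2)Cyclostomata:0.5,(Cmil:1.3,(Drer:1.0,(Lcha:0.8,(Xlae:0.6,((Ggal:0.3,Acar:0.3)Sauropsida:0.2,(Hsap:0.2,Mmus:0.2)Mammalia:0.3)Amniota:0.1)Tetrapoda:0.2)Sarcopterygii:0.2)Osteichthyes:0.3)Gnathostomata:0.4)Vertebrata:0.2)Olfactores:0.3)Chordata;
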
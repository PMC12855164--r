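species,genus,documented
Lupulella mesomelas,Lupulella,1
Tragelaphus oryx,Tragelaphus,1
Tragelaphus strepsiceros,Tragelaphus,1
Tragelaphus angasii,Tragelaphus,1
Anas undulata,Anas,1
Anas erythrorhyncha,Anas,1
Anas smithii,Anas,1
Sarkidiornis melanotos,Sarkidiornis,1
Gyps coprotheres,Gyps,1
Loxodonta africana,Loxodonta,1
Orycteropus afer,Orycteropus,1
Caracal caracal,Caracal,1
Leptailurus serval,Leptailurus,1
Proteles cristata,Proteles,1
Redunca arundinum,Redunca,1
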
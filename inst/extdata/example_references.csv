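species,marker,has_reference
Lupulella mesomelas,12S,1
Tragelaphus oryx,12S,1
Tragelaphus strepsiceros,12S,1
Tragelaphus angasii,12S,1
Anas undulata,12S,0
Anas erythrorhyncha,12S,0
Anas smithii,12S,1
Sarkidiornis melanotos,12S,1
Gyps coprotheres,12S,1
Loxodonta africana,12S,1
Orycteropus afer,12S,1
Caracal caracal,12S,1
Leptailurus serval,12S,0
Proteles cristata,12S,1
Redunca arundinum,12S,0
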
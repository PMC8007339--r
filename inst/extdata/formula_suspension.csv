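material,function_,amount_g
Valzadepine crushed tablets 80/5,Active ingredients,40.00
Aspartame,Sweetening agent,2.00
Mannitol,Flavoring agent,272.00
Trisodium citrate,pH modifier/buffering agent,3.20
Sodium hydroxide,pH modifier/buffering agent,0.20
Guar gum,Suspending agent,3.00
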
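# DTC testing company aliases (case-insensitive whole-token matching,
# spacing variants included for social-media orthography).
23andMe: [23andme, 23 and me]
AncestryDNA: [ancestrydna, ancestry dna]
MyHeritage: [myheritage, my heritage]
FamilyTreeDNA: [familytreedna, family tree dna, ftdna]
LivingDNA: [livingdna, living dna]
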
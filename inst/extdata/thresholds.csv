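analyte,tissue,threshold_value,threshold_high,threshold_basis,threshold_kind,source,dry_mass_factor_applied
As,liver,30.3,,dry,toxic,canine reference compendium,3.03
As,kidney,40,,dry,toxic,canine reference compendium,4
Ca,liver,100,757,dry,adequate,canine reference compendium,3.03
Ca,kidney,2000,,dry,high,canine reference compendium,4
Cd,liver,3.03,21.2,dry,high,canine reference compendium,3.03
Cd,kidney,120,,dry,toxic,terrestrial mammal toxicity review,
Cu,liver,1212,,dry,toxic,canine reference compendium,3.03
Cu,kidney,80,,dry,toxic,canine reference compendium,4
Fe,liver,424,,dry,adequate,canine reference compendium,3.03
Fe,kidney,560,,dry,adequate,canine reference compendium,4
Hg,liver,91,,dry,toxic,mammalian toxicity review,
Hg,kidney,120,,dry,toxic,mammalian toxicity review,
Mn,liver,9.09,15.1,dry,adequate,canine reference compendium,3.03
Mn,kidney,4.8,7.2,dry,adequate,canine reference compendium,4
Pb,liver,25,30,dry,toxic,wildlife lead review,
Pb,kidney,15,,dry,toxic,wildlife lead review,
Pb,bone,25,,dry,toxic,wildlife lead review,
Se,liver,20,,dry,toxic,selenium toxicity review,
Se,kidney,4,6,dry,adequate,canine reference compendium,4
Tl,liver,23.0,,dry,toxic,canine reference compendium,3.03
Tl,kidney,136,,dry,toxic,canine reference compendium,4
U,kidney,4,9.2,dry,toxic,canine reference compendium,4
V,liver,0.09,0.182,dry,adequate,canine reference compendium,3.03
V,kidney,0.12,0.2,dry,adequate,canine reference compendium,4
Zn,liver,1118,,dry,toxic,canine reference compendium,3.03
Zn,kidney,1180,,dry,toxic,canine reference compendium,4
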
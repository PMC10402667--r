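site,patients,fractions,flagged
Larynx,29,641,40
Oropharynx (p16-),27,597,26
Lip and oral cavity,24,530,2
Nasal cavity and sinuses,7,155,7
Unknown primary H&N tumors,7,155,0
Hypopharynx,5,110,1
Nasopharynx,5,110,3
Salivary glands,5,110,3
HPV-mediated (p16+) oropharyngeal cancer,2,44,0
Lacrimal gland,1,22,0
Nervous system (Misc.),1,23,0
Orbit,1,22,0
Thyroid gland,1,22,0
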
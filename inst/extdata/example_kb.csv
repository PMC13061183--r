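drug_a,drug_b,severity
Naproxen,Ketorolac,contraindicated
Diclofenac,Ketorolac,contraindicated
Ibuprofen,Ketorolac,contraindicated
Acetylsalicylic Acid,Metformin,major
Acetylsalicylic Acid,Clopidogrel,major
Acetylsalicylic Acid,Hydrochlorothiazide,major
Acetylsalicylic Acid,Metoprolol,moderate
Metformin,Metoprolol,moderate
Hydrochlorothiazide,Metformin,moderate
Acetylsalicylic Acid,Ketorolac,contraindicated
Naproxen,Ibuprofen,major
Acetaminophen,Naproxen,minor
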
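canonical_name,aliases,is_top_list
Acetylsalicylic Acid,ASA|ASPIRIN,TRUE
Clopidogrel,PLAVIX,TRUE
Metformin,GLUCOPHAGE,TRUE
Metoprolol,LOPRESSOR,TRUE
Naproxen,NAPROSYN,TRUE
Ketorolac,TORADOL,TRUE
Diclofenac,VOLTAREN,TRUE
Ibuprofen,ADVIL|BRUFEN,TRUE
Acetaminophen,TYLENOL|PARACETAMOL,TRUE
Hydrochlorothiazide,HCTZ,TRUE
Hydrocortisone,,FALSE
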
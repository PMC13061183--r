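prescription_id,patient_id,age,sex,specialty,drug_name
RX001,P01,67,M,cardiology,ASPIRIN 80MG TAB
RX001,P01,67,M,cardiology,PLAVIX 75MG
RX001,P01,67,M,cardiology,GLUCOPHAGE 500MG
RX001,P01,67,M,cardiology,LOPRESSOR 50MG
RX001,P01,67,M,cardiology,TYLENOL 500MG
RX002,P02,34,F,orthopedics,NAPROSYN 250MG
RX002,P02,34,F,orthopedics,TORADOL 10MG
RX003,P03,51,F,general practice,HCTZ 25MG
RX003,P03,51,F,general practice,GLUCOPHAGE 1000MG
RX003,P03,51,F,general practice,HYDROCORTISONE CREAM 1%
RX004,P04,8,M,pediatrics,PARACETAMOL SYRUP
RX004,P04,8,M,pediatrics,BRUFEN SYRUP
RX005,P02,34,F,emergency medicine,VOLTAREN 50MG
RX005,P02,34,F,emergency medicine,TORADOL 10MG
RX005,P02,34,F,emergency medicine,TYLENOL 500MG
RX006,P05,45,,general practice,ASPIRIN 80MG
RX006,P05,45,,general practice,GLUCOPHAGE 500MG
RX007,P06,72,F,cardiology,ASPIRIN 80MG
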
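pt,soc,soc_code
Seizure,Nervous system disorders,10029205
Product dose omission issue,"Injury, poisoning and procedural complications",10022117
Fatigue,General disorders and administration site conditions,10018065
Somnolence,Nervous system disorders,10029205
Dizziness,Nervous system disorders,10029205
Fall,"Injury, poisoning and procedural complications",10022117
Feeling abnormal,General disorders and administration site conditions,10018065
Gait disturbance,General disorders and administration site conditions,10018065
Wrong technique in product usage process,"Injury, poisoning and procedural complications",10022117
Balance disorder,Nervous system disorders,10029205
Memory impairment,Nervous system disorders,10029205
Hypersomnia,Nervous system disorders,10029205
Product use issue,"Injury, poisoning and procedural complications",10022117
Vision blurred,Eye disorders,10015919
Diplopia,Eye disorders,10015919
Lethargy,Nervous system disorders,10029205
Generalised tonic-clonic seizure,Nervous system disorders,10029205
Product availability issue,Product issues,10077536
Dysarthria,Nervous system disorders,10029205
Adverse event,General disorders and administration site conditions,10018065
Therapy interrupted,Surgical and medical procedures,10042613
Aura,Nervous system disorders,10029205
Disturbance in attention,Nervous system disorders,10029205
Feeling drunk,General disorders and administration site conditions,10018065
Irritability,Psychiatric disorders,10037175
Amnesia,Nervous system disorders,10029205
Speech disorder,Nervous system disorders,10029205
Anger,Psychiatric disorders,10037175
Abnormal behaviour,Psychiatric disorders,10037175
Partial seizures,Nervous system disorders,10029205
Headache,Nervous system disorders,10029205
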
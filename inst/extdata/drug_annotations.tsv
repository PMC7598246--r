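# stage=extdata published prioritized drug predictions: averaged HepG2 connectivity score vs the Huh7-R-A7 resistance signature, with approval status, targets and action keywords
drug_id	score	status	targets	actions
dasatinib	-0.3073	Approved	ABL1,SRC,EPHA2,LCK,YES1,KIT,PDGFRB,STAT5B,ABL2,FYN	antineoplastic, kinase inhibitor
enzalutamide	-0.3686	Approved	AR	antineoplastic, antiandrogen, receptor antagonist
paclitaxel	-0.2423	Approved	TUBB1,BCL2,NR1I2,MAP4,MAP2,MAPT	antineoplastic, antimicrotubule
palbociclib	-0.2387	Approved	CDK4,CDK6	antineoplastic, kinase inhibitor
pemetrexed	-0.2830	Approved	TYMS,ATIC,DHFR,GART	antineoplastic, antimetabolite, antifolate
toremifene	-0.3114	Approved	ESR1	antiestrogen, antineoplastic, receptor antagonist
aminoglutethimide	-0.3121	Approved	CYP19A1,CYP11A1	adrenocortical suppressant, antineoplastic, aromatase inhibitor
anastrozole	-0.3002	Approved	CYP19A1	antineoplastic, aromatase inhibitor
nilotinib	-0.2677	Approved	ABL1,KIT	antineoplastic, kinase inhibitor
procarbazine	-0.2573	Approved	DNA	antineoplastic, alkylating
thiotepa	-0.3158	Approved	DNA	antineoplastic, alkylating
vemurafenib	-0.3455	Approved	BRAF	antineoplastic, kinase inhibitor
verteporfin	-0.2223	Approved	n/a	antineoplastic, photosensitizer
brivanib	-0.2896	Investigational	VEGFR2,FGFR1,FGFR2	antineoplastic, kinase inhibitor
fostamatinib	-0.2388	Investigational	SYK	antineoplastic, anti-inflammatory, kinase inhibitor
darinaparsin	-0.3833	Investigational	n/a	antineoplastic, organic arsenical
enzastaurin	-0.2693	Investigational	PRKCB	antineoplastic, kinase inhibitor
orteronel	-0.2719	Investigational	CYP17A1	antineoplastic, antiandrogen
quizartinib	-0.3080	Investigational	FLT3	antineoplastic, kinase inhibitor
tipifarnib	-0.4090	Investigational	FNTB	antineoplastic, farnesyltransferase inhibitor
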
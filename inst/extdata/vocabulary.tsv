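code	term	term_type	semantic_type
C0001899	Alanine Transaminase	preferred	(unspecified)
C0005615	Birth	preferred	(unspecified)
C0005821	Blood Platelets	preferred	(unspecified)
C0005890	Body Height	preferred	(unspecified)
C0005910	Body weight	preferred	(unspecified)
C0010294	Creatinine	preferred	(unspecified)
C0011008	Date in time	preferred	(unspecified)
C0027361	Persons	preferred	(unspecified)
C0150831	Patient Sex	preferred	Organism Attribute T032
C0201836	Alanine aminotransferase measurement	preferred	(unspecified)
C0201975	Creatinine measurement	preferred	(unspecified)
C0201976	Creatinine measurement, serum	preferred	(unspecified)
C0421451	Patient date of birth	preferred	(unspecified)
C0475440	Tumor size	preferred	(unspecified)
C0489786	Height	preferred	(unspecified)
C0942474	Platelets:NCnc:Pt:Bld:Qn	preferred	(unspecified)
C1276997	Antidementia drug	preferred	Pharmacologic Substance T121
C1287267	Finding of platelet count	preferred	(unspecified)
C1531592	Antidementia agents	preferred	Pharmacologic Substance T121
C1548569	Gender of Patient	preferred	Intellectual Product T170
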
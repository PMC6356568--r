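gene_id	ensembl_id	region	function_known
Dock6	ENSCPOG00000026620	CDS	yes
Eps8l2	ENSCPOG00000003802	CDS	yes
Hmcn2	ENSCPOG00000013220	CDS	yes
Icam5	ENSCPOG00000000999	CDS	yes
Kcns1	ENSCPOG00000013646	CDS	yes
Klhl10	ENSCPOG00000002818	CDS	yes
Map3k6	ENSCPOG00000012359	CDS	yes
Mmp9	ENSCPOG00000007559	CDS	yes
Myh14	ENSCPOG00000002223	CDS	yes
Notch4	ENSCPOG00000000591	CDS	yes
Otud6a	ENSCPOG00000012916	CDS	yes
Pclo	ENSCPOG00000009376	CDS	yes
Plekhh3	ENSCPOG00000010080	CDS	yes
Sh3gl1	ENSCPOG00000023236	CDS	yes
Sigirr	ENSCPOG00000025549	CDS	yes
Slc46a2	ENSCPOG00000001823	CDS	yes
Sox13	ENSCPOG00000006604	CDS	yes
Med26	ENSCPOG00000008968	CDS	yes
Sncg	ENSCPOG00000023463	Promoter	yes
Svp-1	ENSCPOG00000025237	Promoter	yes
Unknown	ENSCPOG00000022766	Promoter	no
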
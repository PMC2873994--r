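# Class I HLA-A real-time PCR-SSP typing panel (transcribed reaction tables)
locus: HLA-A
reference: NC_000006.10 30018310-30021633

[primers]
name	sequence	location
A226F01	GGCTCYCACTCCATGAGGTATTTC	203-226
A228F01	GGCTCYCACTCCATGAGGTATTTCAC	203-228
A228F02	GGCTCYCACTCCATGAGGTATTTCTA	203-228
A228F03	GGCTCYCACTCCATGAGGTATTTCTC	203-228
A228F04	GGCTCYCACTCCATGAGGTATTTCT[C]	203-228
A228F05	GGCTCYCACTCCATGAGGTATTTCTT	203-228
A228F06	GGCTCYCACTCCATGAGGTATTTCT[T]	203-228
A400R01	TCTGTGASTGGGCCTTCACT	400-419
A400R02	TCTGTGASTGGGCCTTCAT[A]	400-419
A400R03	TCTGTGASTGGGCCTTCACA	400-419
A400R04	TCTGTGASTGGGCCTTCAC[A]	400-419
A402R01	TCTGTGASTGGGCCTTCA	402-419
A429R01	GCAGGGTCCCCAGGTTCT	429-446
A429R02	CGCGATCCGCAGGTTCT	429-444
A429R03	CAGGGTCCCCAGGTTCG	429-445
A429R04	CAGGGTCCCCAGGTCCA	429-445
A734F01	NGTTCTCACACCVTCCAGAGG	714-734
A756F01	GCTGCGACGTGGGGT	742-756
A818F01	GGCAAGGATTACATCGCC	801-818
A819F01	GGCAAGGATTACATCGCCC	801-819
A819F02	GGCAAGGATTACATCGCC[C]	801-819
A819F03	GGCAAGGATTACATCGCC[T]	801-819
A898R01	RCTCTCMRCTGCTCCGCC[T]	898-916
A898R02	RCTCTCMRCTGCTCCGCCA	898-916
A910F01	TCCATTCGGCGGAGCAACG	892-910
A910R02	GCCCTCCAGGTAGRCTCTC[C]	910-929
A910R03	GCCCTCCAGGTAGGCTCTC[A]	910-929
A930R01	GAGCCMSTCCACGCACGT	930-947
A930R02	GAGCCMSTCCACGCACG[T]	930-947
A930R03	AGCCMSTCCACGCACC[G]	930-946
A932R01	GAGCCMSTCCACGCAC	932-947

[probes]
name	dye	quencher	sequence	location
A278P01	FAM	BHQ1	CGCACAAACTGCATGTCGTCCACGTAGCC	278-306
A846P01	TET	BHQ1	TCTGAGCCGCCATGTCCGCCGC	846-867
A921P01	TET	BHQ1	CTGGAGGGCTGCTGCGTGGAGTGG	921-944

[reactions]
id	specific_fwd	specific_rev	specific_probe	internal_fwd	internal_rev	internal_probe	addressed_alleles
HLA-A 001	A228F01	A429R03	A278P01	A818F01	A932R01	A846P01	A*2902
HLA-A 002	A228F02	A429R04	A278P01	A818F01	A932R01	A846P01	A*0205,A*3402,A*6601,A*6802
HLA-A 003	A228F02	A400R01	A278P01	A818F01	A932R01	A846P01	A*0205
HLA-A 004	A228F02	A400R03	A278P01	A818F01	A932R01	A846P01	A*3402,A*6601,A*6802
HLA-A 005	A228F04	A429R02	A278P01	A818F01	A932R01	A846P01	A*2301
HLA-A 006	A228F03	A429R01	A278P01	A818F01	A932R01	A846P01	A*3002
HLA-A 007	A228F05	A400R02	A278P01	A818F01	A932R01	A846P01	A*0101,A*3601
HLA-A 008	A228F06	A400R01	A278P01	A818F01	A932R01	A846P01	A*0201,A*0202
HLA-A 009	A228F06	A400R04	A278P01	A818F01	A932R01	A846P01	A*0301,A*7401
HLA-A 010	A228F06	A429R04	A278P01	A818F01	A932R01	A846P01	A*0201,A*0202,A*0301,A*7401
HLA-A 011	A734F01	A898R02	A846P01	A226F01	A402R01	A278P01	A*0201,A*0202,A*0205,A*6802
HLA-A 012	A819F02	A930R03	A846P01	A226F01	A402R01	A278P01	A*0101,A*6601
HLA-A 013	A819F03	A930R01	A846P01	A226F01	A402R01	A278P01	A*2902,A*7401
HLA-A 014	A910F01	A930R02	A921P01	A226F01	A402R01	A278P01	A*3601
HLA-A 015	A756F01	A898R01	A846P01	A226F01	A402R01	A278P01	A*0301,A*3402
HLA-A 016	A819F02	A910R03	A846P01	A226F01	A402R01	A278P01	A*0201,A*0301,A*2301,A*3001,A*3002,A*3402
HLA-A 017	A756F01	A910R02	A846P01	A226F01	A402R01	A278P01	A*0202,A*0205
HLA-A 018	A819F01	A910R02	A846P01	A226F01	A402R01	A278P01	A*0101,A*0202,A*0205,A*3601,A*6601,A*6802
HLA-A 019	A228F04	A429R04	A278P01	A818F01	A932R01	A846P01	A*3001
HLA-A 020	A228F04	A400R04	A278P01	A818F01	A932R01	A846P01	A*3001,A*3002
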
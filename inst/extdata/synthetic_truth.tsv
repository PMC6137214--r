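locus_id	contig	start0	end0	unit	n_units	with_motifs	motif5p_offset	motif3p_offset
C1R14	chr1	1981	2037	CTTT	14	FALSE	NA	NA
C1R13	chr1	3776	3828	CTTT	13	TRUE	4	4
C1R22	chr1	5106	5194	CTTT	22	FALSE	NA	NA
C1R16	chr1	5304	5368	CTTT	16	FALSE	NA	NA
C1R12	chr1	5867	5915	CTTT	12	FALSE	NA	NA
C1R10	chr1	6226	6266	CTTT	10	FALSE	NA	NA
C1R18	chr1	8476	8548	CTTT	18	FALSE	NA	NA
C1R17	chr1	9746	9814	CTTT	17	TRUE	6	9
C1R19	chr1	10030	10106	CTTT	19	TRUE	9	1
C1R15	chr1	11860	11920	CTTT	15	TRUE	8	4
C2R25	chr2	90	190	CTTT	25	FALSE	NA	NA
C2R13	chr2	675	727	CTTT	13	FALSE	NA	NA
C2R14	chr2	1787	1843	CTTT	14	TRUE	7	10
C2R11	chr2	2083	2127	CTTT	11	FALSE	NA	NA
C2R21	chr2	2897	2981	CTTT	21	TRUE	8	6
C2R16	chr2	4484	4548	CTTT	16	TRUE	11	1
C2R15	chr2	6151	6211	CTTT	15	FALSE	NA	NA
C2R20	chr2	6397	6477	CTTT	20	FALSE	NA	NA
C2R17	chr2	10743	10811	CTTT	17	FALSE	NA	NA
C2R18	chr2	11602	11674	CTTT	18	TRUE	4	9
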
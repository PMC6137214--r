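chr1	1981	2037	C1R14	0	+
chr1	3776	3828	C1R13	0	+
chr1	5106	5194	C1R22	0	+
chr1	5304	5368	C1R16	0	+
chr1	5867	5915	C1R12	0	+
chr1	6226	6266	C1R10	0	+
chr1	8476	8548	C1R18	0	+
chr1	9746	9814	C1R17	0	+
chr1	10030	10106	C1R19	0	+
chr1	11860	11920	C1R15	0	+
chr2	90	190	C2R25	0	+
chr2	675	727	C2R13	0	+
chr2	1787	1843	C2R14	0	+
chr2	2083	2127	C2R11	0	+
chr2	2897	2981	C2R21	0	+
chr2	4484	4548	C2R16	0	+
chr2	6151	6211	C2R15	0	+
chr2	6397	6477	C2R20	0	+
chr2	10743	10811	C2R17	0	+
chr2	11602	11674	C2R18	0	+
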
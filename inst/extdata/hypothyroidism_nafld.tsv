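SNP	CHR	Pos	beta.exposure	se.exposure	pval.exposure	beta.outcome	se.outcome	pval.outcome
rs17020127	1	107815461	-0.2289	0.0306	7.95E-14	-0.2438	0.1347	0.070361
rs181871363	1	113318163	-0.276	0.0456	1.37E-09	-0.2917	0.2025	0.1499
rs11571293	2	203852990	0.1259	0.0215	5.11E-09	0.0757	0.0928	0.4147
rs9860547	3	188411191	-0.1121	0.0205	4.26E-08	-0.0386	0.0888	0.663599
rs1993945	5	77222370	0.1468	0.0201	2.72E-13	0.0558	0.0876	0.5244
rs9272245	6	32635095	0.1458	0.025	5.75E-09	0.2047	0.0927	0.7014
rs9273400	6	32659351	-0.2252	0.022	1.41E-24	-0.1314	0.095	0.1667
rs925489	9	97784318	-0.1887	0.0211	3.31E-19	-0.0102	0.0904	0.9098
rs229536	22	37193829	-0.1172	0.0202	6.70E-09	0.0347	0.0879	0.6933
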
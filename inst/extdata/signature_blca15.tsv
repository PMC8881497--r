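pair	coefficient	HR	HR.95L	HR.95H	p-value
MAFG-DT|SCAT2	0.9052	2.4725	1.4417	4.2397	0.0010
ACTA2-AS1|LINC01705	-0.3363	0.7144	0.4986	1.0235	0.0668
LINC00460|PICSAR	0.3370	1.4007	0.9846	1.9928	0.0610
AL359881.1|AC129926.1	-0.6039	0.5467	0.3653	0.8179	0.0033
LINC01767|AL161431.1	-0.4304	0.6503	0.4532	0.9331	0.0195
AC112721.1|LINC02154	0.3135	1.3682	0.9684	1.9331	0.0754
AC010331.1|TDRKH-AS1	-0.5091	0.6010	0.4273	0.8454	0.0034
AL591848.2|AC100801.1	-0.3116	0.7323	0.4885	1.0977	0.1314
AL591848.2|AC005180.1	-0.7269	0.4834	0.3339	0.6999	0.0001
AL158166.1|AL355916.1	-0.5227	0.5929	0.4152	0.8468	0.0040
AC129926.1|SCAT2	0.5215	1.6846	1.1189	2.5364	0.0125
AF127577.3|SCAT2	0.8895	2.4339	1.6760	3.5346	2.97e-06
LINC02820|AC073365.1	-0.6777	0.5078	0.3566	0.7231	0.0002
AL161772.1|AP005432.2	0.4795	1.6153	1.1057	2.3599	0.0132
NR4A1AS|LINC02195	0.5227	1.6866	1.1873	2.3960	0.0035
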
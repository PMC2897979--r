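name	decay_rate
rnpB	>20
ffs	>20
ssrA	>20
ssrS	>20
Yfr4	>20
Yfr5	>20
Yfr2	>20
asRNA_04601	>20
Yfr16	>20
Yfr8	19.7
Yfr14	11.6
asRNA_17331	8.4
asRNA_17181	7.8
ncRNA_Yfr9	6.9
asRNA_15721	4.9
Yfr11	4.8
asRNA_04001	4.2
Yfr6	4.0
asRNA_38	3.5
asRNA_00641	3.4
asRNA_17971	3.2
Yfr1	3.1
asRNA_07401	2.3
Yfr19	2.2
Yfr13	2.2
asRNA_03431	2.0
Yfr20	2.0
asRNA_02731	1.7
asRNA_18171	1.6
Yfr21	1.5
asRNA_15701	0.9
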
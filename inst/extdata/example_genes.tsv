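#gene_id	chrom	start	end	strand	zone_index	class_I
Olfr0001	chr1	1000000	1002000	+	1.12	0
Olfr0002	chr1	1050000	1052000	-	2.41	0
Olfr0003	chr1	1100000	1102000	+	4.87	0
OlfrI0004	chr1	1150000	1152000	+	1.00	1
Olfr0005	chr2	1000000	1002000	-	2.55	0
Olfr0006	chr2	1050000	1052000	+	3.20	0
Olfr0007	chr2	1100000	1102000	+	4.96	0
Olfr0008	chr2	3100000	3102000	-	1.77	0
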